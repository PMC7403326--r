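# Fixtures are built in code: digitized spheres, tilted slabs, and an
# independent marching-cubes mesh-area oracle (scikit-image via the system
# python) used only to cross-check the Crofton estimator.

make_sphere <- function(r, spacing = 1, pad = 6, center_offset = c(0, 0, 0)) {
  n <- ceiling(2 * r / spacing) + 2 * pad
  idx <- ((0:(n - 1)) - (n - 1) / 2) * spacing
  d2 <- outer(outer((idx - center_offset[1])^2, (idx - center_offset[2])^2, `+`),
              (idx - center_offset[3])^2, `+`)
  binary_volume(array(d2 <= r^2, dim = c(n, n, n)), spacing)
}

# slab tilted by `angle_deg` about the y axis (surface height varies with x)
make_tilted_slab <- function(angle_deg, n = 160, spacing = 2, base = 100) {
  xw <- (0:(n - 1)) * spacing
  tmap <- matrix(base + tan(angle_deg * pi / 180) * xw, n, n, byrow = TRUE)
  binary_volume(mucosurf:::cpp_occ_from_height(tmap, spacing, n), spacing)
}

# mesh surface area via marching cubes on the lightly smoothed occupancy
# (standard practice for binary data), in um^2
mc_area_python <- function(bin, sigma = 1) {
  tf <- tempfile(fileext = ".tif")
  write_volume(bin, tf)
  on.exit(unlink(c(tf, paste0(tf, ".meta"))))
  sp <- bin$spacing
  py <- sprintf("
import tifffile, numpy as np
from scipy.ndimage import gaussian_filter
from skimage import measure
v = tifffile.imread(r'%s').astype(np.float32) / 255.0
v = gaussian_filter(v, sigma=%g)
verts, faces, _, _ = measure.marching_cubes(v, level=0.5, spacing=(%g, %g, %g))
print(float(measure.mesh_surface_area(verts, faces)))
", tf, sigma, sp[1], sp[2], sp[3])
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE, stderr = TRUE)
  val <- suppressWarnings(as.numeric(out[length(out)]))
  if (is.na(val)) stop("marching-cubes oracle failed: ", paste(out, collapse = "\n"))
  val
}

# split a raw NRRD file into header lines and the data blob
split_nrrd_raw <- function(raw_all) {
  nl <- which(raw_all == as.raw(10L))
  i <- which(diff(nl) == 1L)[1]
  stopifnot(!is.na(i))
  list(hdr = strsplit(rawToChar(raw_all[seq_len(nl[i] - 1L)]), "\n")[[1]],
       data = raw_all[(nl[i] + 2L):length(raw_all)])
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
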