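finger_bin <- function(h = 300, crypt = 150, slab = crypt + 100, n = 352) {
  nz <- ceiling((slab + h) / 2) + 30
  spec <- phantom_spec("finger_villi", volume_dims = c(nz, n, n),
                       voxel_spacing = 2, villus_height = h,
                       crypt_depth = crypt, slab_thickness = slab)
  list(spec = spec, vol = generate_phantom(spec))
}

morph_section <- function(fb) {
  plane <- mucosurf:::auto_section_plane(fb$vol, fb$spec, NULL)
  extract_section(fb$vol, plane)
}

test_that("lattice-aligned sections reproduce stored slices exactly", {
  set.seed(7)
  v <- voxel_volume(array(sample(0:255, 40^3, TRUE) + 0, c(40, 40, 40)), 2)
  # plane normal -y through integer index 15 (y = 30 um), u = x, v = +z
  pl <- section_plane(point = c(40, 30, 40), normal = c(0, -1, 0),
                      u = c(0, 0, 1), extent = c(0.06, 0.06), pixel_spacing = 2)
  for (interp in c("nearest", "linear")) {
    sec <- extract_section(v, pl, interp = interp)
    expect_equal(dim(sec$values), c(31, 31))
    stored <- t(v$values[6:36, 16, 6:36])  # [i_u = x, j_v = z]
    expect_equal(sec$values, unname(stored))
  }
  # 90-degree rotated plane (normal +x) picks the orthogonal stored slice
  pl2 <- section_plane(point = c(40, 40, 40), normal = c(0, 0, 1),
                       u = c(0, 1, 0), extent = c(0.06, 0.06), pixel_spacing = 2)
  sec2 <- extract_section(v, pl2, interp = "nearest")
  stored2 <- t(v$values[6:36, 6:36, 21])  # [i_u = y, j_v = z]
  expect_equal(sec2$values, unname(stored2))
})

test_that("a plane through a sphere's center recovers the disk area", {
  sph <- make_sphere(30, spacing = 1, pad = 8)
  ctr <- (dim(sph$occupancy) - 1) / 2
  pl <- section_plane(point = ctr, normal = c(0, -1, 0), u = c(0, 0, 1),
                      extent = c(0.07, 0.07), pixel_spacing = 1)
  sec <- extract_section(sph, pl)
  npix <- sum(sec$values > 0)
  expect_rel(npix, pi * 30^2, 0.02)
})

test_that("planes outside the volume raise an extent error", {
  v <- voxel_volume(array(0, c(20, 20, 20)), 2)
  pl <- section_plane(point = c(20, 20, 20), normal = c(0, -1, 0),
                      u = c(0, 0, 1), extent = c(0.2, 0.2), pixel_spacing = 2)
  expect_error(extract_section(v, pl), class = "mucosurf_error_extent")
})

test_that("measure_pair computes Euclidean landmark distances", {
  p <- measure_pair(NULL, tip = c(0, 600), junction = c(0, 300),
                    base = c(0, 150))
  expect_equal(p$vh, 300)
  expect_equal(p$crd, 150)
  # collinearity is not required
  p2 <- measure_pair(NULL, tip = c(10, 600), junction = c(0, 300),
                     base = c(0, 150))
  expect_equal(p2$vh, sqrt(10^2 + 300^2))
  expect_warning(measure_pair(NULL, tip = c(1, 1), junction = c(1, 1),
                              base = c(0, 0)), "coincide")
})

test_that("landmarks outside the section bounds are rejected", {
  fb <- finger_bin(n = 224)
  sec <- morph_section(fb)
  expect_error(measure_pair(sec, tip = c(-5, 100), junction = c(0, 50),
                            base = c(0, 10)), class = "mucosurf_error_extent")
})

test_that("compute_vhcd applies the three-pair rule and the strict 2.0 cutoff", {
  mk <- function(vh, crd) measure_pair(NULL, tip = c(0, vh), junction = c(0, 0),
                                       base = c(0, -crd))
  boundary <- compute_vhcd(list(mk(300, 150), mk(310, 150), mk(290, 150)))
  expect_equal(boundary$ratio, 2.0)
  expect_equal(boundary$label, "normal_morphometry")  # strict <

  lesion <- compute_vhcd(list(mk(100, 200), mk(100, 200), mk(100, 200)))
  expect_equal(lesion$ratio, 0.5)
  expect_equal(lesion$label, "diagnostic_lesion")

  expect_error(compute_vhcd(list(mk(1, 1), mk(1, 1))),
               class = "mucosurf_error_insufficient_pairs")
})

test_that("compute_vhcd is permutation invariant and scale equivariant", {
  set.seed(11)
  mk <- function(vh, crd) measure_pair(NULL, tip = c(0, vh), junction = c(0, 0),
                                       base = c(0, -crd))
  pairs <- list(mk(310, 140), mk(280, 160), mk(330, 150), mk(290, 145))
  r1 <- compute_vhcd(pairs)
  r2 <- compute_vhcd(sample(pairs))
  expect_equal(r1$ratio, r2$ratio)
  scaled <- lapply(pairs, function(p)
    measure_pair(NULL, p$tip * 3, p$junction * 3, p$base * 3))
  expect_equal(compute_vhcd(scaled)$ratio, r1$ratio)
  # ratio-of-means vs mean-of-ratios are both exposed
  r3 <- compute_vhcd(pairs, method = "mean_of_ratios")
  expect_equal(r3$ratio, mean(vapply(pairs, function(p) p$vh / p$crd, 1)))
})

test_that("auto landmarks recover phantom VH:CrD across the geometry grid", {
  for (g in list(c(300, 150), c(400, 100), c(200, 200))) {
    fb <- finger_bin(h = g[1], crypt = g[2])
    pairs <- auto_landmarks(morph_section(fb))
    expect_gte(length(pairs), 3)
    res <- compute_vhcd(pairs)
    expect_rel(res$ratio, g[1] / g[2], 0.05)
  }
})

test_that("degenerate sections fail with informative morphometry errors", {
  flat <- generate_phantom(phantom_spec("flat_slab",
    volume_dims = c(64, 128, 128), voxel_spacing = 2, slab_thickness = 60))
  pl <- mucosurf:::auto_section_plane(flat, NULL, NULL)
  expect_error(auto_landmarks(extract_section(flat, pl)),
               class = "mucosurf_error_insufficient_pairs")

  # smooth sinusoid relief has villi but no crypts: crd undefined.
  # The section runs along x through a crest row of the egg-crate.
  sine <- phantom_spec("sinusoid", volume_dims = c(224, 96, 512),
                       voxel_spacing = 2, slab_thickness = 100,
                       villus_height = 300, wavelength = 250)
  sv <- generate_phantom(sine)
  pl2 <- section_plane(point = c((224 - 1) * 2 / 2, 62.5, (512 - 1) * 2 / 2),
                       normal = c(0, -1, 0), u = c(0, 0, 1),
                       extent = c(0.9, 0.42), pixel_spacing = 2)
  sec <- extract_section(sv, pl2)
  pairs <- auto_landmarks(sec)
  expect_true(all(is.na(vapply(pairs, `[[`, 1, "crd"))))
  expect_error(compute_vhcd(pairs), class = "mucosurf_error_missing_crypts")
})

test_that("landmark files round-trip into measured pairs", {
  df <- data.frame(
    sample = "s1", section_id = 1L,
    pair_id = rep(1:3, each = 3),
    role = rep(c("tip", "junction", "base"), 3),
    x_um = c(0, 0, 0, 120, 125, 125, 250, 250, 255),
    y_um = c(600, 300, 150, 610, 305, 150, 590, 300, 145)
  )
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  pairs <- landmarks_to_pairs(read_landmarks(p))[["s1/1"]]
  expect_length(pairs, 3)
  expect_equal(pairs[[1]]$vh, 300)
  res <- compute_vhcd(pairs)
  expect_equal(res$n_pairs, 3)
  bad <- df[df$role != "junction" | df$pair_id != 2, ]
  write.csv(bad, p, row.names = FALSE)
  expect_error(landmarks_to_pairs(read_landmarks(p)), class = "mucosurf_error_io")
})
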