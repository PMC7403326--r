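#' Read and write volumetric images with voxel-spacing metadata
#'
#' Two plain formats are supported. `"nrrd"` is the preferred,
#' self-describing choice: a single `.nrrd` file whose text header records
#' sizes, element type, encoding (`raw` or `gzip`) and the physical voxel
#' spacing. `"tiff_stack"` writes a multi-page TIFF plus a mandatory sidecar
#' key-value text file (`<path>.meta`) carrying the spacing, because TIFF
#' resolution tags are too dialect-prone to trust for measurements in mm^2.
#' Reading a TIFF without its sidecar raises a metadata error rather than
#' silently assuming 1 um voxels.
#'
#' On disk the fastest axis is x (the usual image convention); in memory
#' volumes are `[z, y, x]`. Integer grids (uint8, uint16) round-trip
#' bit-exactly; binary volumes are stored as 0/255 uint8 and restored as
#' [binary_volume()] via a `kind: binary` metadata key.
#'
#' @param path file path. Format is inferred from the extension
#'   (`.nrrd` vs `.tif`/`.tiff`) when `format` is omitted.
#' @param format `"nrrd"` or `"tiff_stack"`.
#' @param vol a [voxel_volume()] or [binary_volume()].
#' @param dtype element type for grayscale data: `"uint8"`, `"uint16"` or
#'   `"double"`. Ignored for binary volumes (always uint8 0/255).
#' @return `read_volume()` returns a [voxel_volume()] or [binary_volume()];
#'   `write_volume()` returns `path` invisibly.
#' @examples
#' v <- voxel_volume(array(sample(0:255, 4^3, TRUE), c(4, 4, 4)), c(2, 2, 2))
#' p <- tempfile(fileext = ".nrrd")
#' write_volume(v, p)
#' identical(read_volume(p)$values, v$values)
#' @export
read_volume <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (!file.exists(path))
    msf_stop(sprintf("file not found: %s", path), "error_io")
  if (format == "nrrd") read_nrrd(path) else read_tiff_stack(path)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, format = NULL, dtype = "uint16") {
  format <- infer_format(path, format)
  if (!dir.exists(dirname(path)))
    msf_stop(sprintf("parent directory does not exist: %s", dirname(path)),
             "error_io")
  binary <- inherits(vol, "binary_volume")
  if (!binary && !inherits(vol, "voxel_volume"))
    msf_stop("vol must be a voxel_volume or binary_volume", "error_type")
  if (binary) {
    vals <- cpp_map_levels(vol$occupancy, 0, 255)
    dtype <- "uint8"
  } else {
    vals <- vol$values
    rng <- range(vals)
    if (dtype == "uint8" && (rng[1] < 0 || rng[2] > 255 || any(vals != round(vals))))
      msf_stop("values outside uint8 range or non-integer; use dtype='double'",
               "error_dtype")
    if (dtype == "uint16" && (rng[1] < 0 || rng[2] > 65535 || any(vals != round(vals))))
      msf_stop("values outside uint16 range or non-integer; use dtype='double'",
               "error_dtype")
    if (!dtype %in% c("uint8", "uint16", "double"))
      msf_stop(sprintf("unsupported dtype '%s'", dtype), "error_dtype")
  }
  if (format == "nrrd") {
    write_nrrd(vals, vol$spacing, vol$origin, path, dtype, binary)
  } else {
    write_tiff_stack(vals, vol$spacing, vol$origin, path, dtype, binary)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) {
    if (!format %in% c("nrrd", "tiff_stack"))
      msf_stop(sprintf("unsupported format '%s'", format), "error_io")
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") return("nrrd")
  if (ext %in% c("tif", "tiff")) return("tiff_stack")
  msf_stop(sprintf("cannot infer format from extension '.%s'", ext), "error_io")
}

## ---- NRRD ------------------------------------------------------------------
## Minimal NRRD support: 3D, little-endian, raw or gzip encodings,
## types uint8 / uint16 / double. Sizes on disk are (nx, ny, nz), x fastest.

write_nrrd <- function(vals, spacing, origin, path, dtype, binary) {
  perm <- aperm(vals, c(3, 2, 1))  # (x, y, z), x fastest in column-major
  type <- switch(dtype, uint8 = "uint8", uint16 = "uint16", double = "double")
  hdr <- c(
    "NRRD0004",
    "# mucosurf volume",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %d %d %d", dim(perm)[1], dim(perm)[2], dim(perm)[3]),
    "encoding: raw",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
            spacing[3], spacing[2], spacing[1]),
    sprintf("space origin: (%.10g,%.10g,%.10g)", origin[3], origin[2], origin[1]),
    "space units: \"um\" \"um\" \"um\"",
    if (binary) "mucosurf.kind:=binary" else "mucosurf.kind:=grayscale"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeChar("\n", con, eos = NULL)  # blank line separating header from data
  v <- as.vector(perm)
  if (dtype == "uint8") {
    writeBin(as.raw(v), con)
  } else if (dtype == "uint16") {
    iv <- as.integer(v)
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L  # two's complement for writeBin
    writeBin(iv, con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 8L, endian = "little")
  }
}

read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line (\n\n)
  nl <- which(raw_all == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end))
    msf_stop("malformed NRRD: no blank line terminating the header", "error_io")
  hdr <- strsplit(rawToChar(raw_all[seq_len(hdr_end - 1L)]), "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD", hdr[1]))
    msf_stop("not an NRRD file (missing magic)", "error_io")
  fields <- list()
  for (ln in hdr[-1]) {
    if (grepl("^#", ln) || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(key) {
    if (is.null(fields[[key]]))
      msf_stop(sprintf("NRRD header missing required field '%s'", key),
               "error_metadata")
    fields[[key]]
  }
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L)
    msf_stop("only 3D NRRD volumes are supported", "error_io")
  type <- need("type")
  encoding <- need("encoding")
  spacing_xyz <- nrrd_spacing(fields)
  origin_xyz <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin_xyz <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                      ",")[[1]])
  }
  data_raw <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (encoding == "gzip" || encoding == "gz") {
    data_raw <- memDecompress(data_raw, type = "gzip")
  } else if (encoding != "raw") {
    msf_stop(sprintf("unsupported NRRD encoding '%s'", encoding), "error_io")
  }
  n <- prod(sizes)
  endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
  v <- switch(type,
    uint8 = readBin(data_raw, "integer", n = n, size = 1L, signed = FALSE),
    uint16 = readBin(data_raw, "integer", n = n, size = 2L, signed = FALSE,
                     endian = endian),
    double = readBin(data_raw, "double", n = n, size = 8L, endian = endian),
    msf_stop(sprintf("unsupported NRRD type '%s'", type), "error_io")
  )
  if (length(v) < n)
    msf_stop("NRRD data shorter than promised by header", "error_io")
  arr <- aperm(array(v, dim = sizes), c(3, 2, 1))  # back to (z, y, x)
  spacing <- rev(spacing_xyz)
  origin <- rev(origin_xyz)
  kind <- fields[["mucosurf.kind"]]
  if (identical(kind, "binary")) {
    binary_volume(arr > 127, spacing, origin)
  } else {
    voxel_volume(arr, spacing, origin)
  }
}

nrrd_spacing <- function(fields) {
  if (!is.null(fields[["space directions"]])) {
    toks <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(toks) != 3L)
      msf_stop("NRRD 'space directions' must have three vectors", "error_metadata")
    M <- t(vapply(toks, function(t)
      as.numeric(strsplit(gsub("[()]", "", t), ",")[[1]]), numeric(3)))
    off <- M; diag(off) <- 0
    if (any(abs(off) > 1e-9))
      msf_stop("non-axis-aligned NRRD space directions are not supported",
               "error_metadata")
    sp <- abs(diag(M))
  } else if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else {
    msf_stop("NRRD header missing voxel spacing ('space directions' or 'spacings')",
             "error_metadata")
  }
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
    msf_stop("invalid NRRD voxel spacing", "error_metadata")
  sp
}

## ---- TIFF stack ------------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".meta")

write_tiff_stack <- function(vals, spacing, origin, path, dtype, binary) {
  if (dtype == "double")
    msf_stop("TIFF stacks support integer data only; use format='nrrd' for double",
             "error_dtype")
  bits <- if (dtype == "uint8") 8L else 16L
  scale <- 2^bits - 1
  scaled <- cpp_scale01(vals, 1 / scale)
  pages <- lapply(seq_len(dim(vals)[1]), function(i)
    matrix(scaled[i, , ], nrow = dim(vals)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  meta <- c(
    sprintf("spacing_z_um: %.10g", spacing[1]),
    sprintf("spacing_y_um: %.10g", spacing[2]),
    sprintf("spacing_x_um: %.10g", spacing[3]),
    sprintf("origin_z_um: %.10g", origin[1]),
    sprintf("origin_y_um: %.10g", origin[2]),
    sprintf("origin_x_um: %.10g", origin[3]),
    sprintf("kind: %s", if (binary) "binary" else "grayscale"),
    sprintf("dtype: %s", dtype)
  )
  writeLines(meta, sidecar_path(path))
}

read_tiff_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    msf_stop(sprintf(
      "TIFF stack '%s' has no spacing sidecar '%s' (required keys spacing_z_um, spacing_y_um, spacing_x_um); refusing to assume 1 um voxels",
      path, sc), "error_metadata")
  kv <- read_keyvalue(sc)
  for (key in c("spacing_z_um", "spacing_y_um", "spacing_x_um"))
    if (is.null(kv[[key]]))
      msf_stop(sprintf("sidecar '%s' missing required key '%s'", sc, key),
               "error_metadata")
  spacing <- as.numeric(c(kv$spacing_z_um, kv$spacing_y_um, kv$spacing_x_um))
  origin <- as.numeric(c(kv$origin_z_um %||% 0, kv$origin_y_um %||% 0,
                         kv$origin_x_um %||% 0))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(0L, dim = d)
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  if (identical(kv$kind, "binary")) {
    binary_volume(arr > 127, spacing, origin)
  } else {
    voxel_volume(arr, spacing, origin)
  }
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) out[[trimws(kv[2])]] <- trimws(kv[3])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write phantom ground truth as a key-value text file
#'
#' @param gt a `ground_truth` object from [analytic_surface_area()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  writeLines(sprintf("%s: %.10g", names(gt), unlist(gt)), path)
  invisible(path)
}
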