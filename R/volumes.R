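#' Voxel volume containers
#'
#' `voxel_volume()` wraps a 3D scalar intensity grid together with its physical
#' voxel spacing; `binary_volume()` does the same for a tissue/background
#' occupancy grid. Arrays are indexed `[z, y, x]` (z axial, pointing towards
#' the gut lumen) and the world coordinate of voxel `(i, j, k)` (0-based) is
#' `(i * sz, j * sy, k * sx)` micrometres.
#'
#' @param values 3D numeric array of intensities, indexed `[z, y, x]`.
#' @param occupancy 3D logical array, `TRUE` = tissue.
#' @param spacing numeric length-3, voxel spacing `(sz, sy, sx)` in
#'   micrometres; all entries must be positive.
#' @param origin numeric length-3 world offset in micrometres (default 0).
#' @return An object of class `voxel_volume` or `binary_volume`: a list with
#'   elements `values` (or `occupancy`), `spacing`, `origin`.
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(v$values)
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  check_geometry(dim(values), spacing, origin)
  if (!is.numeric(values)) msf_stop("values must be numeric", "error_type")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' @rdname voxel_volume
#' @export
binary_volume <- function(occupancy, spacing, origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  check_geometry(dim(occupancy), spacing, origin)
  if (!is.logical(occupancy)) {
    occupancy <- array(as.logical(occupancy != 0), dim = dim(occupancy))
  }
  structure(list(occupancy = occupancy, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_volume")
}

check_geometry <- function(dims, spacing, origin) {
  if (length(dims) != 3L || any(dims < 2L))
    msf_stop("volume must be 3D with at least 2 voxels per axis", "error_geometry")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    msf_stop("spacing must be three positive values (sz, sy, sx) in um",
             "error_geometry")
  if (length(origin) != 3L || any(!is.finite(origin)))
    msf_stop("origin must be three finite values", "error_geometry")
  invisible(TRUE)
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d (z,y,x), spacing %s um, range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("<binary_volume> %d x %d x %d (z,y,x), spacing %s um, %.1f%% tissue\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              100 * mean(x$occupancy)))
  invisible(x)
}

vol_dims <- function(vol) {
  if (inherits(vol, "binary_volume")) dim(vol$occupancy) else dim(vol$values)
}

# lateral world extent (y, x) spanned by voxel cells, in um
lateral_extent <- function(vol) {
  d <- vol_dims(vol)
  c(y = d[2] * vol$spacing[2], x = d[3] * vol$spacing[3])
}

#' Dice overlap between two binary volumes
#'
#' @param a,b `binary_volume` objects with identical dimensions.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "binary_volume"), inherits(b, "binary_volume"),
            identical(dim(a$occupancy), dim(b$occupancy)))
  inter <- sum(a$occupancy & b$occupancy)
  2 * inter / (sum(a$occupancy) + sum(b$occupancy))
}
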