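#' Denoise a grayscale volume with a 3D non-local-means filter
#'
#' Each voxel is replaced by a weighted average of voxels in a cubic search
#' window, with weights decaying in the squared distance between the cubic
#' intensity patches around the two voxels
#' (`w = exp(-||P_i - P_j||^2 / (strength^2 |P|))`). Compared with a
#' Gaussian blur of equal variance reduction, patch weighting preserves the
#' tissue boundary gradient, which is what the downstream surface estimate
#' depends on.
#'
#' The filter parameters are not prescribed by any scanner convention; the
#' defaults (patch radius 1, search radius 3, strength matched to the noise
#' level) were chosen so that the render - denoise - segment chain recovers
#' phantom occupancy with Dice >= 0.99 at the noise levels the phantoms
#' emulate.
#'
#' @param vol a [voxel_volume()].
#' @param patch_radius,search_radius cubic patch and search radii in voxels
#'   (`>= 1`).
#' @param strength filter strength `h` in intensity units (`> 0`); a good
#'   default is about the noise standard deviation.
#' @return A denoised [voxel_volume()] of identical geometry.
#' @export
denoise_nl <- function(vol, patch_radius = 1L, search_radius = 3L, strength = 10) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (patch_radius < 1L || search_radius < 1L)
    msf_stop("patch_radius and search_radius must be >= 1 voxel", "error_config")
  if (!is.finite(strength) || strength <= 0)
    msf_stop("strength must be positive", "error_config")
  out <- cpp_nlm3d(vol$values, as.integer(patch_radius),
                   as.integer(search_radius), strength)
  voxel_volume(out, vol$spacing, vol$origin)
}

#' Denoise a grayscale volume with a 3D median filter
#'
#' Rank-filter semantics: each voxel becomes the median of the cubic
#' neighborhood of radius `radius` (clamped at volume borders).
#'
#' @param vol a [voxel_volume()].
#' @param radius neighborhood radius in voxels (`>= 1`).
#' @return A filtered [voxel_volume()].
#' @export
denoise_median <- function(vol, radius = 1L) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (radius < 1L) msf_stop("radius must be >= 1 voxel", "error_config")
  voxel_volume(cpp_median3d(vol$values, as.integer(radius)),
               vol$spacing, vol$origin)
}

#' Segment tissue from background by thresholding
#'
#' Reproduces manual thresholding as an explicit numeric threshold; with
#' `threshold = "auto"` the threshold maximising Otsu's between-class
#' variance on a 256-bin histogram is used instead. Tissue is the bright
#' (`>=` threshold) class by default, matching contrast-stained micro-CT in
#' which tissue takes up the stain; set `polarity = "dark"` to invert.
#' Optionally only the largest 26-connected tissue component is retained.
#'
#' @param vol a [voxel_volume()].
#' @param threshold numeric threshold in intensity units, or `"auto"`.
#' @param polarity `"bright"` (tissue >= threshold) or `"dark"`.
#' @param keep_largest retain only the largest connected tissue component?
#' @return A [binary_volume()].
#' @export
segment <- function(vol, threshold = "auto", polarity = c("bright", "dark"),
                    keep_largest = FALSE) {
  stopifnot(inherits(vol, "voxel_volume"))
  polarity <- match.arg(polarity)
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(vol$values)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L)
      msf_stop("threshold must be a single number or 'auto'", "error_config")
    rng <- range(vol$values)
    if (threshold < rng[1] - diff(rng) || threshold > rng[2] + diff(rng))
      msf_stop("manual threshold far outside the intensity range", "error_config")
  }
  occ <- cpp_threshold(vol$values, threshold, polarity == "bright")
  if (keep_largest && any(occ)) {
    lab <- cpp_label3d(occ)
    counts <- tabulate(lab[lab > 0L])
    occ <- array(lab == which.max(counts), dim = dim(occ))
  }
  out <- binary_volume(occ, vol$spacing, vol$origin)
  attr(out, "threshold") <- threshold
  out
}

# Otsu's criterion on a 256-bin histogram of the intensity range.
otsu_threshold <- function(vals) {
  rng <- range(vals)
  if (rng[1] == rng[2])
    msf_stop("cannot auto-threshold a constant volume (degenerate histogram)",
             "error_degenerate")
  nb <- 256L
  edges <- seq(rng[1], rng[2], length.out = nb + 1L)
  h <- tabulate(pmin(nb, pmax(1L, findInterval(vals, edges, all.inside = TRUE))),
                nbins = nb)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(nb + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # the criterion is flat across an empty valley: take the middle of the tie
  ties <- which(sigma_b >= max(sigma_b) - 1e-12 * max(sigma_b))
  k <- ties[ceiling(length(ties) / 2)]
  edges[k + 1L]  # tissue is the > k class; threshold at the bin's upper edge
}

#' Label connected tissue components (26-connectivity)
#'
#' @param bin a [binary_volume()].
#' @return Integer array of component labels (0 = background), same dims.
#' @export
label_components <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  cpp_label3d(bin$occupancy)
}
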