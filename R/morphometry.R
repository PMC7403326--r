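#' Define an orientated section plane
#'
#' A digital section through the volume: a plane given by a world point, an
#' orthonormal in-plane frame `(u, v)` plus normal, a lateral extent and a
#' pixel spacing. For morphometry sections the convention is that `v`
#' points lumen-ward (axial up), so that a tissue height profile can be
#' read along `u`.
#'
#' @param point world coordinates `(z, y, x)` of the section center, um.
#' @param normal plane normal `(z, y, x)`; an in-plane frame is completed
#'   from it unless `u` is also given.
#' @param u optional in-plane axis; the second axis is `normal x u`.
#' @param extent section extent `(along u, along v)` in mm (length 1 or 2).
#' @param pixel_spacing section pixel size in um.
#' @return A `section_plane` object.
#' @export
section_plane <- function(point, normal, u = NULL, extent = c(0.5, 0.5),
                          pixel_spacing = 2) {
  if (length(extent) == 1L) extent <- rep(extent, 2L)
  if (any(extent <= 0) || pixel_spacing <= 0)
    msf_stop("extent and pixel_spacing must be positive", "error_config")
  n <- normalize(normal)
  if (is.null(u)) {
    seed_axis <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    u <- normalize(seed_axis - sum(seed_axis * n) * n)
  } else {
    u <- normalize(u)
    if (abs(sum(u * n)) > 1e-6)
      msf_stop("u must be orthogonal to the normal", "error_config")
  }
  v <- cross_zyx(n, u)
  structure(list(point = as.numeric(point), u = u, v = v, normal = n,
                 extent_mm = extent, pixel_spacing = pixel_spacing),
            class = "section_plane")
}

#' Extract a digital section from a volume
#'
#' Resamples the volume on the plane's pixel grid. Grayscale volumes default
#' to trilinear interpolation, binary volumes to nearest-neighbour (so the
#' section stays binary). Lattice-aligned planes at integer indices
#' reproduce the stored slice exactly in both modes.
#'
#' @param vol a [voxel_volume()] or [binary_volume()].
#' @param plane a [section_plane()].
#' @param interp `"nearest"` or `"linear"`; default depends on the input.
#' @return A `section_image`: `values` matrix indexed `[i_u, j_v]`,
#'   `pixel_spacing` (um), `binary` flag, and the `plane` as provenance.
#' @export
extract_section <- function(vol, plane, interp = NULL) {
  stopifnot(inherits(plane, "section_plane"))
  binary <- inherits(vol, "binary_volume")
  if (is.null(interp)) interp <- if (binary) "nearest" else "linear"
  if (!interp %in% c("nearest", "linear"))
    msf_stop("interp must be 'nearest' or 'linear'", "error_config")
  vals <- if (binary) cpp_as_double(vol$occupancy) else vol$values
  ps <- plane$pixel_spacing
  nu <- max(2L, floor(plane$extent_mm[1] * 1000 / ps) + 1L)
  nv <- max(2L, floor(plane$extent_mm[2] * 1000 / ps) + 1L)
  out <- cpp_resample_plane(vals, vol$spacing, plane$point, plane$u, plane$v,
                            nu, nv, ps, if (interp == "nearest") 0L else 1L)
  if (anyNA(out))
    msf_stop("section plane footprint extends outside the volume", "error_extent")
  if (binary) out <- matrix(out > 0.5, nrow(out), ncol(out)) * 1
  structure(list(values = out, pixel_spacing = ps, binary = binary,
                 plane = plane), class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px @ %.3g um, %s\n", nrow(x$values),
              ncol(x$values), x$pixel_spacing,
              if (x$binary) "binary" else "grayscale"))
  invisible(x)
}

#' Measure one villus-crypt pair from landmarks
#'
#' Villous height is the Euclidean distance from the villus tip to the
#' villus-crypt junction; crypt depth the distance from the junction to the
#' crypt base. Landmarks are 2D points `(x, y)` in um in section
#' coordinates; they need not be collinear.
#'
#' @param section a [extract_section()] image (used for bounds checking),
#'   or `NULL` to skip the check.
#' @param tip,junction,base numeric length-2 landmarks `(x, y)` um.
#' @return A `villus_crypt_pair`: the landmarks plus `vh`, `crd` (um; `crd`
#'   is `NA` when `base` is `NA`, i.e. no crypt).
#' @export
measure_pair <- function(section = NULL, tip, junction, base) {
  pts <- list(tip = tip, junction = junction, base = base)
  if (!is.null(section)) {
    stopifnot(inherits(section, "section_image"))
    lim <- (dim(section$values) - 1) * section$pixel_spacing
    for (nm in names(pts)) {
      p <- pts[[nm]]
      if (all(is.na(p))) next
      if (p[1] < 0 || p[1] > lim[1] || p[2] < 0 || p[2] > lim[2])
        msf_stop(sprintf("landmark '%s' lies outside the section", nm),
                 "error_extent")
    }
  }
  vh <- sqrt(sum((tip - junction)^2))
  if (vh == 0)
    warning("villus tip and junction coincide: vh = 0", call. = FALSE)
  crd <- if (all(is.na(base))) NA_real_ else sqrt(sum((junction - base)^2))
  structure(list(tip = tip, junction = junction, base = base,
                 vh = vh, crd = crd), class = "villus_crypt_pair")
}

#' Villous height / crypt depth ratio with the diagnostic rule
#'
#' Averages at least three individual villus-crypt pairs and labels the
#' result: a VH:CrD strictly below the `cutoff` (default 2.0) is
#' `diagnostic_lesion`, otherwise `normal_morphometry` (a ratio of exactly
#' 2.0 is not diagnostic). The default ratio is the ratio of means,
#' `mean(VH) / mean(CrD)`, which is robust to a single short crypt;
#' `method = "mean_of_ratios"` averages the per-pair ratios instead.
#'
#' @param pairs list of [measure_pair()] results (at least 3).
#' @param cutoff diagnostic threshold (strict `<`).
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return A `morphometry_result`: `pairs`, `n_pairs`, `mean_vh`,
#'   `mean_crd`, `ratio`, `label`.
#' @export
compute_vhcd <- function(pairs, cutoff = 2.0,
                         method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  if (inherits(pairs, "villus_crypt_pair")) pairs <- list(pairs)
  if (length(pairs) < 3L)
    msf_stop(sprintf(
      "morphometry requires at least three villus-crypt pairs (got %d)",
      length(pairs)), "error_insufficient_pairs")
  vh <- vapply(pairs, `[[`, numeric(1), "vh")
  crd <- vapply(pairs, `[[`, numeric(1), "crd")
  if (anyNA(crd))
    msf_stop("crypt depth is undefined for some pairs (no crypts); VH:CrD is undefined",
             "error_missing_crypts")
  ratio <- if (method == "ratio_of_means") mean(vh) / mean(crd)
           else mean(vh / crd)
  structure(list(pairs = pairs, n_pairs = length(pairs),
                 mean_vh = mean(vh), mean_crd = mean(crd), ratio = ratio,
                 label = if (ratio < cutoff) "diagnostic_lesion"
                         else "normal_morphometry"),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> n = %d pairs, VH %.0f um, CrD %.0f um, VH:CrD = %.2f (%s)\n",
              x$n_pairs, x$mean_vh, x$mean_crd, x$ratio, x$label))
  invisible(x)
}

#' Automatic landmark detection on a binary section
#'
#' Automates on phantoms what is otherwise done by hand: from the tissue
#' height profile along the section, local maxima become villus tips. In
#' each gap between consecutive tips the villus-crypt junction level is the
#' modal profile height (the histogram bin, of width `crypt_min_depth`,
#' holding the most profile samples, refined to the median of that bin;
#' ties resolve to the lower level). A flat inter-villus plateau dominates
#' this histogram, whereas a smooth trough without crypts concentrates mass
#' at its bottom, so the junction level coincides with the saddle in both
#' cases. The profile minimum becomes a crypt base when it dips at least
#' `crypt_min_depth` below the junction level, and the junction landmark is
#' then placed at the crypt-mouth shoulder (the nearest profile point to
#' the crypt that regains the junction level). Pairs are returned sorted
#' left to right. The heuristic is validated on phantoms only; on real
#' scans manual landmarks govern.
#'
#' @param section a binary [extract_section()] image with `v` axial-up.
#' @param min_prominence minimum tip height above the junction level, um.
#' @param min_separation minimum lateral distance between tips, um.
#' @param crypt_min_depth minimum dip below the junction level for a crypt
#'   to be recognised, um.
#' @return List of `villus_crypt_pair` objects (`crd = NA` where no crypt
#'   was found).
#' @export
auto_landmarks <- function(section, min_prominence = 50, min_separation = 50,
                           crypt_min_depth = 20) {
  stopifnot(inherits(section, "section_image"))
  if (!section$binary)
    msf_stop("auto_landmarks requires a binary section", "error_type")
  ps <- section$pixel_spacing
  vals <- section$values
  nu <- nrow(vals)
  prof <- apply(vals, 1, function(col) {
    w <- which(col > 0)
    if (length(w)) (max(w) - 1) * ps else NA_real_
  })
  if (anyNA(prof))
    msf_stop("section does not contain a connected mucosal profile",
             "error_degenerate")
  xs <- (seq_len(nu) - 1) * ps

  # local maxima with a minimum-separation window
  w <- max(1L, round(min_separation / ps))
  is_peak <- vapply(seq_len(nu), function(i) {
    lo <- max(1L, i - w); hi <- min(nu, i + w)
    prof[i] == max(prof[lo:hi])
  }, logical(1))
  # collapse plateau runs of peaks to their centers
  peaks <- integer(0)
  i <- 1L
  while (i <= nu) {
    if (is_peak[i]) {
      j <- i
      while (j < nu && is_peak[j + 1L] && prof[j + 1L] == prof[i]) j <- j + 1L
      peaks <- c(peaks, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }

  if (length(peaks) < 2L)
    msf_stop("fewer than 3 detectable villus-crypt pairs on this section",
             "error_insufficient_pairs")

  pairs <- list()
  for (g in seq_len(length(peaks) - 1L)) {
    a <- peaks[g]; b <- peaks[g + 1L]
    gap <- (a + 1L):(b - 1L)
    if (length(gap) < 3L) next
    gv <- prof[gap]
    # modal profile level in the gap = junction (saddle plateau) level
    bw <- crypt_min_depth
    bins <- floor((gv - min(gv)) / bw)
    counts <- table(bins)
    top <- as.integer(names(counts)[counts == max(counts)])
    modal <- min(top)  # ties resolve to the lower level
    junction_level <- median(gv[bins == modal])
    base_i <- gap[which.min(gv)]
    has_crypt <- junction_level - prof[base_i] >= crypt_min_depth
    tip_i <- if (prof[a] >= prof[b]) a else b
    if (prof[tip_i] - junction_level < min_prominence) next
    if (has_crypt) {
      # crypt-mouth shoulder: nearest point towards the tip that regains
      # the junction level
      step <- if (tip_i < base_i) -1L else 1L
      j_i <- base_i
      while ((j_i + step) %in% gap &&
             prof[j_i] < junction_level - ps) j_i <- j_i + step
      junction <- c(xs[j_i], junction_level)
      base <- c(xs[base_i], prof[base_i])
    } else {
      junction <- c(xs[base_i], junction_level)
      base <- c(NA_real_, NA_real_)
    }
    tip <- c(xs[tip_i], prof[tip_i])
    pairs[[length(pairs) + 1L]] <- measure_pair(NULL, tip = tip,
                                                junction = junction, base = base)
  }
  if (length(pairs) < 3L)
    msf_stop("fewer than 3 detectable villus-crypt pairs on this section",
             "error_insufficient_pairs")
  pairs
}

#' Read and write landmark tables
#'
#' Landmark files are delimited text with columns `sample`, `section_id`,
#' `pair_id`, `role` (one of `tip`, `junction`, `base`), `x_um`, `y_um`.
#'
#' @param path file path (comma- or tab-delimited; see `sep`).
#' @param sep field separator.
#' @return `read_landmarks()`: a data.frame. `landmarks_to_pairs()`: a named
#'   list (per sample/section) of lists of [measure_pair()] results.
#' @export
read_landmarks <- function(path, sep = ",") {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample", "section_id", "pair_id", "role", "x_um", "y_um")
  missing <- setdiff(need, names(df))
  if (length(missing))
    msf_stop(sprintf("landmark file missing columns: %s",
                     paste(missing, collapse = ", ")), "error_io")
  if (!all(df$role %in% c("tip", "junction", "base")))
    msf_stop("landmark roles must be tip, junction or base", "error_io")
  df
}

#' @rdname read_landmarks
#' @param df a landmark data.frame as returned by `read_landmarks()`.
#' @export
landmarks_to_pairs <- function(df) {
  out <- list()
  for (key in unique(paste(df$sample, df$section_id, sep = "/"))) {
    sub <- df[paste(df$sample, df$section_id, sep = "/") == key, ]
    pairs <- lapply(sort(unique(sub$pair_id)), function(pid) {
      p <- sub[sub$pair_id == pid, ]
      get_pt <- function(role) {
        r <- p[p$role == role, ]
        if (nrow(r) == 0) {
          if (role == "base") return(c(NA_real_, NA_real_))
          msf_stop(sprintf("pair %s in %s lacks a '%s' landmark", pid, key, role),
                   "error_io")
        }
        c(r$x_um[1], r$y_um[1])
      }
      measure_pair(NULL, tip = get_pt("tip"), junction = get_pt("junction"),
                   base = get_pt("base"))
    })
    out[[key]] <- pairs
  }
  out
}
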