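chain_phantom <- function() {
  spec <- phantom_spec("sinusoid", volume_dims = c(96, 80, 80),
                       voxel_spacing = 4, slab_thickness = 100,
                       villus_height = 200, wavelength = 250)
  generate_phantom(spec)
}

test_that("non-local means is a near-fixed point on clean two-level input", {
  truth <- chain_phantom()
  clean <- render_grayscale(truth, noise_sigma = 0, blur_sigma = 0)
  dn <- denoise_nl(clean, patch_radius = 1, search_radius = 2, strength = 10)
  expect_lt(max(abs(dn$values - clean$values)), 1)
  expect_identical(dim(dn$values), dim(clean$values))
  expect_error(denoise_nl(clean, strength = 0), class = "mucosurf_error_config")
})

test_that("non-local means removes noise while preserving the mean intensity", {
  truth <- chain_phantom()
  noisy <- render_grayscale(truth, noise_sigma = 15, blur_sigma = 0, seed = 3)
  dn <- denoise_nl(noisy, patch_radius = 1, search_radius = 2, strength = 15)
  interior <- mucosurf:::cpp_erode3d(truth$occupancy, 3L)
  expect_lt(var(dn$values[interior]), 0.4 * var(noisy$values[interior]))
  expect_rel(mean(dn$values), mean(noisy$values), 0.01)
})

test_that("median filter matches a brute-force rank filter and is idempotent-ish", {
  set.seed(5)
  v <- voxel_volume(array(runif(14^3, 0, 100), c(14, 14, 14)), 2)
  md <- denoise_median(v, 1)
  bf <- array(0, c(14, 14, 14))
  for (x in 1:14) for (y in 1:14) for (z in 1:14) {
    nb <- v$values[max(1, z - 1):min(14, z + 1),
                   max(1, y - 1):min(14, y + 1),
                   max(1, x - 1):min(14, x + 1)]
    bf[z, y, x] <- median(nb)
  }
  expect_equal(md$values, bf)

  const <- voxel_volume(array(7, c(10, 10, 10)), 2)
  expect_identical(denoise_median(const, 1)$values, const$values)

  # single-voxel impulse in a constant field is removed at radius 1
  imp <- array(10, c(10, 10, 10)); imp[5, 5, 5] <- 200
  out <- denoise_median(voxel_volume(imp, 2), 1)
  expect_equal(out$values[5, 5, 5], 10)
})

test_that("segmentation thresholds behave and are monotone in the threshold", {
  truth <- chain_phantom()
  g <- render_grayscale(truth, noise_sigma = 10, blur_sigma = 0, seed = 9)
  s1 <- segment(g, threshold = 110)
  s2 <- segment(g, threshold = 140)
  expect_true(all(s2$occupancy <= s1$occupancy))  # raising never adds tissue

  lo <- segment(g, threshold = min(g$values))
  expect_true(all(lo$occupancy))
  hi <- segment(g, threshold = max(g$values) + 1)
  expect_false(any(hi$occupancy))

  expect_error(segment(voxel_volume(array(5, c(4, 4, 4)), 2), "auto"),
               class = "mucosurf_error_degenerate")
})

test_that("Otsu auto threshold separates the rendered classes and matches EBImage", {
  truth <- chain_phantom()
  g <- render_grayscale(truth, noise_sigma = 12, blur_sigma = 0, seed = 2)
  seg <- segment(g, "auto")
  thr <- attr(seg, "threshold")
  expect_gt(thr, 80)
  expect_lt(thr, 170)
  # independent implementation on the same data, scaled to [0, 1]; the Otsu
  # criterion is flat across the empty inter-class valley, so thresholds are
  # compared through the segmentations they induce
  rng <- range(g$values)
  img <- EBImage::Image((as.vector(g$values) - rng[1]) / diff(rng),
                        dim = c(length(g$values), 1))
  thr_eb <- EBImage::otsu(img, range = c(0, 1), levels = 256) * diff(rng) + rng[1]
  seg_eb <- segment(g, threshold = thr_eb)
  expect_gt(dice(seg, seg_eb), 0.999)
})

test_that("render-denoise-segment chain recovers phantom occupancy (Dice >= 0.99)", {
  truth <- chain_phantom()
  g <- render_grayscale(truth, noise_sigma = 20, blur_sigma = 0, seed = 4)
  dn <- denoise_nl(g, patch_radius = 1, search_radius = 2, strength = 20)
  seg <- segment(dn, threshold = 125)
  expect_gte(dice(seg, truth), 0.99)
})

test_that("largest-component cleanup drops disconnected debris", {
  spec <- phantom_spec("flat_slab", volume_dims = c(48, 40, 40),
                       voxel_spacing = 2, slab_thickness = 40)
  occ <- generate_phantom(spec)$occupancy
  occ[40, 5, 5] <- TRUE  # floating speck
  g <- render_grayscale(binary_volume(occ, 2), noise_sigma = 0, blur_sigma = 0)
  seg <- segment(g, threshold = 125, keep_largest = TRUE)
  expect_false(seg$occupancy[40, 5, 5])
  expect_equal(max(label_components(seg)), 1L)
})
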