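test_that("flat slab voxelises to the expected axial layers", {
  spec <- phantom_spec("flat_slab", volume_dims = c(128, 48, 48),
                       voxel_spacing = 2, slab_thickness = 100)
  vol <- generate_phantom(spec)
  # 100 um slab at 2 um voxels, center-in-solid: layers z = 0..49
  expect_true(all(vol$occupancy[1:50, , ]))
  expect_false(any(vol$occupancy[51:128, , ]))
})

test_that("sinusoid with zero amplitude degenerates to the flat slab", {
  base <- list(volume_dims = c(96, 40, 40), voxel_spacing = 2,
               slab_thickness = 100)
  flat <- generate_phantom(do.call(phantom_spec, c(kind = "flat_slab", base)))
  sin0 <- generate_phantom(do.call(phantom_spec,
    c(kind = "sinusoid", base, villus_height = 0)))
  expect_identical(sin0$occupancy, flat$occupancy)
})

test_that("finger phantom places the expected villus grid", {
  # 0.5 x 0.5 mm base with 125 um pitch -> 4 x 4 = 16 villi
  spec <- phantom_spec("finger_villi", volume_dims = c(304, 250, 250),
                       voxel_spacing = 2, crypt_depth = 0)
  vol <- generate_phantom(spec)
  above <- vol$occupancy
  above[seq_len(ceiling(spec$slab_thickness / 2) + 1), , ] <- FALSE
  lab <- label_components(binary_volume(above, vol$spacing))
  expect_equal(max(lab), 16L)
})

test_that("phantom generation is deterministic and validates geometry", {
  spec <- phantom_spec("finger_villi", volume_dims = c(304, 96, 96),
                       voxel_spacing = 2)
  expect_identical(generate_phantom(spec)$occupancy,
                   generate_phantom(spec)$occupancy)
  expect_error(phantom_spec("flat_slab", volume_dims = c(16, 32, 32),
                            voxel_spacing = 2, slab_thickness = 100),
               class = "mucosurf_error_config")
  expect_error(phantom_spec("finger_villi", villus_radius = 70,
                            villus_pitch = 125),
               class = "mucosurf_error_config")
})

test_that("analytic areas: flat slab and finger closed forms", {
  flat <- phantom_spec("flat_slab", volume_dims = c(128, 250, 250),
                       voxel_spacing = 2, slab_thickness = 100)
  gt <- analytic_surface_area(flat, 500)
  expect_equal(gt$analytic_area_mm2, 0.25)
  expect_equal(gt$expected_coefficient, 1.0)

  # cylinder + hemispherical cap closed form, 16 villi under a 0.5 mm square
  fing <- phantom_spec("finger_villi", volume_dims = c(304, 250, 250),
                       voxel_spacing = 2, villus_height = 300,
                       villus_radius = 25, crypt_depth = 0)
  gtf <- analytic_surface_area(fing, 500)
  r <- 0.025; hcyl <- 0.275
  expected <- 0.25 + 16 * (-pi * r^2 + 2 * pi * r * hcyl + 2 * pi * r^2)
  expect_equal(gtf$analytic_area_mm2, expected, tolerance = 1e-12)

  # crypt wells add wall + floor - mouth = 2 pi r_c d each
  fingc <- phantom_spec("finger_villi", volume_dims = c(304, 250, 250),
                        voxel_spacing = 2, crypt_depth = 150, crypt_radius = 15)
  gtc <- analytic_surface_area(fingc, 500)
  n_crypts <- 3 * 4  # x = 125, 250, 375 between villi; 4 villus rows in y
  expect_equal(gtc$analytic_area_mm2 - gtf$analytic_area_mm2,
               n_crypts * 2 * pi * 0.015 * 0.150 / 1, tolerance = 1e-9)
  expect_equal(gtc$expected_ratio, 2.0)
})

test_that("sinusoid quadrature agrees across resolutions and increases with h", {
  spec <- phantom_spec("sinusoid", volume_dims = c(344, 288, 288),
                       voxel_spacing = 2, slab_thickness = 100,
                       villus_height = 300, wavelength = 250)
  gt <- analytic_surface_area(spec, 500)
  # independent fixed-grid Simpson evaluation at two resolutions
  k <- 2 * pi / 250; a <- 150
  f <- function(x, y) sqrt(1 + (a * k * cos(k * x) * sin(k * y))^2 +
                             (a * k * sin(k * x) * cos(k * y))^2)
  c0 <- (288 - 1) * 2 / 2
  q1 <- pracma::simpson2d(f, c0 - 250, c0 + 250, c0 - 250, c0 + 250, nx = 128, ny = 128)
  q2 <- pracma::simpson2d(f, c0 - 250, c0 + 250, c0 - 250, c0 + 250, nx = 256, ny = 256)
  expect_rel(q1, q2, 1e-3)
  expect_rel(gt$analytic_area_mm2, q2 / 1e6, 1e-3)

  areas <- vapply(c(100, 200, 300), function(h) {
    s <- phantom_spec("sinusoid", volume_dims = c(344, 288, 288),
                      voxel_spacing = 2, slab_thickness = 100,
                      villus_height = h, wavelength = 250)
    analytic_surface_area(s, 500)$analytic_area_mm2
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("finger voxel volume matches the analytic solid volume within 2%", {
  spec <- phantom_spec("finger_villi", volume_dims = c(304, 250, 250),
                       voxel_spacing = 2, crypt_depth = 0)
  vol <- generate_phantom(spec)
  above <- vol$occupancy
  above[seq_len(125), , ] <- FALSE  # strip the slab (z < 250 um)
  vox_vol <- sum(above) * prod(vol$spacing)
  r <- 25; hcyl <- 275
  analytic <- 16 * (pi * r^2 * hcyl + 2 / 3 * pi * r^3)
  expect_rel(vox_vol, analytic, 0.02)
})

test_that("grayscale rendering is reproducible with matched noise statistics", {
  spec <- phantom_spec("flat_slab", volume_dims = c(64, 48, 48),
                       voxel_spacing = 2, slab_thickness = 60)
  vol <- generate_phantom(spec)
  clean <- render_grayscale(vol, noise_sigma = 0, blur_sigma = 0)
  expect_true(all(clean$values %in% c(50, 200)))
  expect_identical(clean$values > 125, vol$occupancy)

  g1 <- render_grayscale(vol, noise_sigma = 10, blur_sigma = 2, seed = 42)
  g2 <- render_grayscale(vol, noise_sigma = 10, blur_sigma = 2, seed = 42)
  expect_identical(g1$values, g2$values)

  # within-class noise sd on eroded interiors ~ noise_sigma
  er <- mucosurf:::cpp_erode3d(vol$occupancy, 4L)
  expect_rel(sd(g1$values[er]), 10, 0.05)
  bg <- mucosurf:::cpp_erode3d(array(!vol$occupancy, dim = dim(vol$occupancy)), 4L)
  expect_rel(sd(g1$values[bg]), 10, 0.05)
})
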