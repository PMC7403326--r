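# mucosurf

Quantitative morphometry of small-bowel mucosal biopsies from micro-CT
volumes.

Conventional histology grades duodenal biopsies on 2D sections, where the
villous height to crypt depth ratio (VH:CrD, diagnostic below 2.0) depends
critically on cutting the specimen at the right angle. A contrast-enhanced
micro-CT scan of the same biopsy yields a full 3D reconstruction at ~2 um
voxels, from which sections can be cut digitally at any angle and — more
importantly — the mucosal **surface area** can be measured directly.
`mucosurf` implements that pipeline for researchers working with (or
simulating) volumetric biopsy images:

* **Synthetic mucosal phantoms** (flat slab, sinusoidal relief,
  finger villi with crypt wells) with closed-form or quadrature ground
  truth for surface area and VH:CrD, so every stage is testable without
  scan data.
* **Volume IO**: multi-page TIFF (with a mandatory spacing sidecar) and
  NRRD, lossless for integer grids, with physical voxel spacing in um.
* **Preprocessing**: 3D non-local-means and median denoising, manual or
  Otsu thresholding, largest-component cleanup.
* **Surface quantification**: surface area inside an orientated
  measurement rectangle by a discretized Crofton formula (2x2x2
  configuration lookup table, 13 lattice directions with calibrated
  weights), reported as the *effective surface area coefficient*

  ```
  coefficient = measured surface area in rectangle (mm^2)
                / area of the rectangle (mm^2)
  ```

  whose theoretical minimum is 1.0 for perfectly flat mucosa, plus a
  replicate protocol (20 random placements per ROI side, 0.1–1.0 mm,
  means and 95% CIs) for ROI-size consistency.
* **Morphometry**: arbitrarily orientated digital sections, landmark-based
  villus/crypt measurements, the ≥3-pair averaging rule and the strict
  VH:CrD < 2.0 diagnostic label; automatic landmarking on phantoms.
* **Pipeline**: a YAML-driven `run_sample()` producing deterministic,
  provenance-stamped per-sample reports, plus a thin CLI
  (`inst/cli/mucosurf`).

## Worked example

A healthy-mucosa phantom: finger villi 300 um tall on a 125 um grid with
150 um crypts (true VH:CrD = 2.0), voxelised at 2 um:

```r
library(mucosurf)
spec <- phantom_spec("finger_villi", volume_dims = c(304, 352, 352),
                     voxel_spacing = 2)
vol  <- generate_phantom(spec)
vol
#> <binary_volume> 304 x 352 x 352 (z,y,x), spacing 2 x 2 x 2 um, 45.0% tissue

lut  <- build_lut(13, spacing = vol$spacing)
rect <- place_rectangle(vol, side_u = 0.5)       # 0.5 x 0.5 mm, auto-aligned
effective_surface_area(vol, rect, lut)
#> <surface_estimate> 1.2083 mm^2 over 0.2500 mm^2: coefficient 4.833

analytic_surface_area(spec, 500)$expected_coefficient
#> [1] 4.795044
```

The measured coefficient (4.833) is within 0.8% of the phantom's analytic
truth and sits in the range expected for healthy villous mucosa; a flat
slab gives 1.000. The full pipeline adds automatic morphometry on a digital
section through a villus row:

```r
run_sample(list(sample_id = "demo",
  phantom = list(kind = "finger_villi", volume_dims = c(304, 352, 352),
                 voxel_spacing = 2),
  auto_morphometry = TRUE, rect_side_mm = 0.5, seed = 1))
#> <sample_report> demo: coefficient 4.833 (1.2083 mm^2 / 0.2500 mm^2), VH:CrD 2.03 (normal_morphometry)
```

The recovered VH:CrD of 2.03 is within 1.5% of the constructed 2.0, and the
label applies the strict < 2.0 cutoff. See
`vignettes/mucosurf-methods.Rmd` for the estimator, its calibration, and
the design decisions.

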