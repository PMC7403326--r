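---
title: "Quantifying mucosal surface area and VH:CrD from micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mucosal surface area and VH:CrD from micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucosurf)
```

## The measurement problem

Small-bowel biopsies are conventionally graded on 2D histological sections,
where the villous height to crypt depth ratio (VH:CrD) is the standard
quantitative readout and a ratio below 2.0 indicates celiac-type villous
atrophy. Sectioning is orientation-sensitive: obliquely cut villi shorten,
crypts become circles, and borderline lesions are misread. Contrast-enhanced
micro-CT of the same biopsies yields a full 3D reconstruction at roughly
2 um voxels, from which one can (a) cut digital sections at any angle for
morphometry, and (b) measure something a section can never give: the
mucosal *surface area*. The statistic of interest is the
**effective surface area coefficient**,

$$\mathrm{coefficient} \;=\;
\frac{\text{measured surface area inside an orientated rectangle (mm}^2)}
     {\text{area of the rectangle itself (mm}^2)},$$

whose theoretical minimum is 1.0 for perfectly flat mucosa; healthy villous
relief raises it several-fold. `mucosurf` implements this pipeline -
segmentation, rectangle placement, surface estimation, replicate statistics,
digital sectioning, VH:CrD - and, because no public micro-CT biopsy volumes
exist, validates every stage on synthetic mucosal phantoms with analytic
ground truth.

## Surface area by a discretized Crofton formula

The Crofton identity relates the area of a surface to the expected number of
intersections with random test lines. On the voxel lattice, test lines run
along 13 discrete directions (3 axes, 6 face diagonals, 4 body diagonals),
an intersection is a tissue/background transition between neighbouring
voxels, and the whole estimator folds into a 256-entry lookup table over
2x2x2 voxel configurations:

$$\hat S \;=\; 2 \sum_d w_d \frac{v}{\lambda_d} N_d
\;=\; \sum_{\text{2x2x2 cells}} L[\mathrm{config}],$$

with $v$ the voxel volume, $\lambda_d$ the lattice step along direction $d$,
$N_d$ the transition count, and the table built by distributing each
transition over the cells that contain its edge (axis edges belong to 4
cells, face diagonals to 2, body diagonals to 1). The table satisfies
$L[\varnothing] = L[\text{full}] = 0$, $L \ge 0$, and complement symmetry.

### Direction weights: density versus calibrated

For a flat interface with unit normal $n$ the estimator responds with
$R(n) = 2\sum_d w_d\,|u_d \cdot n|$ per unit true area, which can be
evaluated in closed form. The classical spherical-Voronoi *density* weights
(available as `weighting = "density"`) give $\int R \, d n = 1$ - unbiased
for isotropically orientated surfaces such as digitized spheres - but
$R = 0.927$ for lattice-aligned interfaces: a flat mucosal slab would read
7% below its true area, and the flat-mucosa anchor of 1.0 would be missed.
Because measurement rectangles are by construction aligned with the mucosa,
the default `"calibrated"` weights re-solve the three weight classes under
two exact constraints - $R(\text{axis}) = 1$ and spherical mean of $R$
equal to 1 (isotropic unbiasedness retained) - using the remaining degree
of freedom to minimise $\max_n |R(n) - 1|$ over a dense deterministic
orientation set. The frozen values (per direction pair) are 0.03222088
(axis), 0.08457623 (face diagonal), 0.09897 (body diagonal).

The price of pinning the axis response is a larger worst-case ripple:
$R$ ranges over about [0.92, 1.05], and a mucosal base tilted 10 degrees
from the lattice reads about +4%. Surfaces that mix orientations average
this ripple out: digitized spheres come out within 0.2% of $4\pi r^2$ at
$r = 30$ voxels, and steep egg-crate relief lands within about 2% of
high-resolution quadrature. For strongly tilted specimens, resampling the
volume so the mucosal base is near lattice-aligned removes the residual
angular error; this is the same operating regime the measurement protocol
assumes.

The 3-direction variant is the textbook axis-count estimator; it under-reads
aligned flat interfaces by 1/3 and is kept only as an independent
cross-check in the test-suite (where it is verified against a direct
transition-count oracle).

### The measurement prism

`place_rectangle()` fits a least-squares plane to the tissue height field
(topmost tissue voxel per lateral column), orients the normal lumen-ward,
and spans the prism from just above the tallest tissue down to just below
the deepest interface (crypt floors included), padded by 3 voxels. Area is
accumulated over 2x2x2 cells whose *center* falls inside the half-open
prism. Two details matter:

* Only genuine tissue/background transitions are tabulated, so the prism's
  artificial cut faces contribute nothing and padding the prism deeper into
  solid tissue changes the estimate by well under 0.5%.
* The half-open cell-center rule counts exactly `side / spacing` cells per
  lattice row for commensurate rectangles. An all-corners-inside rule would
  count only $(n-1)^2$ of $n^2$ cells across an $n$-spacing side - a
  $-4\%$ bias at 0.1 mm sides with 2 um voxels - which is why the center
  rule is used.

Crypt lumen walls inside the prism count toward the measured area: they are
genuine tissue-background interface. Whether a proprietary implementation
would include them is not documented anywhere we can check; the choice is
explicit here and the phantoms' analytic areas account for it.

### Replicate protocol

`replicate_analysis()` reproduces the ROI-size study: square rectangles of
side 0.1-1.0 mm, `n = 20` placements at uniformly random in-plane offsets
(one shared orientation and depth, so placement variance is isolated from
orientation variance), mean and Student-t 95% confidence interval per side.
On a periodic sinusoid phantom the means for sides >= 0.5 mm agree within a
fraction of a percent while CIs below 0.5 mm widen by an order of
magnitude - the ROI-size consistency pattern the method relies on. The
placement rule and the t-interval are package choices; only "means and 95%
confidence intervals of 20 measurements" is externally fixed.

## Synthetic phantoms and what they do (not) emulate

Three families share one contract: a tissue slab topped by relief, voxelised
with a center-in-solid rule at (by default) 2 um isotropic voxels, the
resolution of the imaging protocol being emulated.

* `flat_slab` - the theoretical-minimum reference, coefficient exactly 1.
* `sinusoid` - egg-crate relief $z = t + \frac{h}{2}(1 + \sin ky \sin kx)$;
  its analytic area is the graph integral
  $\iint \sqrt{1 + |\nabla z|^2}$, evaluated by Simpson quadrature with a
  resolution-doubling check at 0.1%. Smooth, periodic, and strictly
  monotone in $h$ - ideal for consistency and monotonicity checks.
* `finger_villi` - cylindrical villi (radius 25 um, pitch 125 um) with
  hemispherical caps, total protrusion `villus_height`, on a square grid;
  cylindrical crypt wells (radius 15 um) sunk into the slab between villi.
  Closed-form area: each villus adds $2\pi r h_{cyl} + 2\pi r^2 - \pi r^2$,
  each crypt $2\pi r_c d_c$. Defaults (villi 300 um, crypts 150 um,
  slab 250 um) give VH:CrD = 2.0, the diagnostic boundary, and sit inside
  the normal ranges reported for human duodenum.

`render_grayscale()` maps occupancy to two intensity levels (tissue bright,
as in iodine-stained scans), applies a Gaussian blur of physical width and
additive Gaussian noise under a fixed seed. This emulates contrast and
noise *levels*, not the physics: no beam hardening, ring artifacts,
reconstruction streaks, partial-volume texture, or stain gradients.
Likewise the geometry is idealised - real villi merge and branch into
complex structures that can reduce surface area at normal VH:CrD; the
phantom family deliberately excludes this (closed-form truth would be
lost), so passing tests demonstrate correctness of the estimators on known
geometry, not robustness to every morphology a biopsy can present.

## Preprocessing

The denoising step mirrors standard practice on contrast-enhanced scans: a
3D non-local-means filter (patch radius 1, search radius 3, strength of the
order of the noise sigma) as the primary choice, with a 3D median filter as
the tested alternative. The non-local parameters are fixed by the
phantom-recovery property - the render / denoise / segment chain must
reach Dice >= 0.99 against ground truth at two-level contrast 50/200 and
noise sigma up to 20 - rather than by fidelity to any particular vendor
implementation, whose parameters are not published. Segmentation is an
explicit numeric threshold (reproducing "manual thresholding"
deterministically) or Otsu's criterion on a 256-bin histogram; with two
well-separated classes the Otsu objective is flat across the empty valley,
so ties resolve to the middle of the tied run. Tissue is the bright class
by default (`polarity` flips it), and an optional largest-component cleanup
(26-connectivity) removes debris.

## Digital sections and VH:CrD

`extract_section()` resamples any orientated plane (nearest-neighbour for
binary, trilinear for grayscale volumes); lattice-aligned planes reproduce
stored slices exactly in both modes. `compute_vhcd()` enforces the
morphometric rules: at least three villus-crypt pairs, ratio =
mean(VH)/mean(CrD) (robust to one short crypt; `method = "mean_of_ratios"`
exposes the alternative), and the *strict* < 2.0 diagnostic cutoff - a
ratio of exactly 2.0 is not diagnostic.

`auto_landmarks()` automates landmarking on phantom sections only: villus
tips are local maxima of the tissue height profile; in each inter-tip gap
the junction level is the modal profile height (histogram bin of width
`crypt_min_depth`, ties to the lower level, refined to the bin median) -
a flat plateau dominates that histogram, while a smooth cryptless trough
concentrates at its bottom, so the level lands on the saddle in both cases;
a crypt is recognised when the profile dips >= 20 um below the junction
level, and the junction landmark sits at the crypt-mouth shoulder. How a
histologist locates the junction on a digital section is genuinely
under-specified; manual landmark files govern on real data, and the
heuristic claims validity only on phantoms, where it recovers VH:CrD within
5% across (height, depth) = (300,150), (400,100), (200,200) um.

## Numerical and reproducibility choices

* Axis order is `[z, y, x]`, z axial and lumen-pointing; world coordinate =
  index x spacing (um). One convention, stated everywhere.
* All intervals (prism membership, thresholds) are half-open, so boundary
  voxels are never double-counted and translation invariance is exact on
  the flat phantom.
* Randomness (rendering noise, replicate placements) flows from explicit
  seeds through a scoped RNG that restores the caller's state; fixed
  configuration and seed give byte-identical phantoms, reports and
  replicate tables.
* The pipeline archives the resolved configuration next to its outputs and
  stamps reports with the MD5 of the analysis-relevant configuration
  (output paths excluded), so identical analyses match byte for byte across
  directories.
* Sinusoid quadrature uses Simpson rules at 256 and 512 nodes per axis and
  insists on 0.1% agreement; phantom test volumes are a few hundred voxels
  per axis (e.g. 512 x 512 x 128 for the flat baseline, 576 x 576 x 224 for
  the replicate study), sizes at which every stage completes in seconds
  while digitization error stays well below the tolerances being tested.

## Known limitations

* The angular response ripple of any 13-direction lattice estimator
  (about +/-5-8% at the most unfavourable orientations) is inherent to the
  direction set; the calibration moves the exact points to where the
  protocol operates (lattice-aligned mucosa, isotropic average).
* Villous merging/branching, patchy lesions and scan artifacts are outside
  the phantom family; conclusions about them require real data.
* `auto_landmarks()` is a phantom tool; it makes no claim of equivalence
  with expert wet-histology landmarking.
* Anisotropic voxels are supported throughout the IO and geometry layer,
  but the calibrated weights assume isotropic spacing; anisotropic volumes
  fall back to density weights (and a warning-free explicit choice).
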