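---
title: "Methods: outline morphometrics and axial asymmetry in leafmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outline morphometrics and axial asymmetry in leafmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafmorph)
```

## The measurement problem

Mechanically stimulated ("touched") plants develop smaller, more
asymmetric leaf blades than undisturbed controls. Quantifying that from
flatbed scans requires three things: a reliable blade mask with physical
calibration, a shape representation that discards position, scale,
rotation and digitisation artefacts while keeping biologically meaningful
contour detail, and statistics that contrast treatment-associated
variation with the natural leaf-to-leaf variation of the same plant.
`leafmorph` implements this chain and, because no scan corpus is bundled,
ships a synthetic-scan generator whose ground truth is expressed in the
same shape basis that the measurement uses.

## Mask extraction

A scan is converted to luminance with ITU-R BT.601 weights
(Y = 0.299 R + 0.587 G + 0.114 B) and binarised at the Otsu threshold —
the cut maximising between-class variance of the 256-level histogram,
found by exhaustive scan (`otsu_threshold()` is checked in the tests
against an independent brute-force implementation). The darker class is
the blade, since leaves are scanned against a near-white background.
Cleaning fills interior holes first (background regions not 4-connected
to the border) and then keeps the largest 8-connected component,
discarding specks below `min_component_px` (default 100 px at 1200 dpi);
the order is recorded in the mask's provenance log. Petiole removal is a
caller-supplied exclusion polygon (interactive editing is out of scope;
the sidecar-CSV contract replaces it).

The outer contour is traced along pixel *cracks* (cell edges), not pixel
centres: the traced polygon's shoelace area then equals the foreground
pixel count exactly for a hole-free component, which makes the polygon
and pixel-count area estimates consistent by construction. Orientation is
canonicalised to positive signed area with the start vertex at the
lexicographically smallest (y, x) corner — EFD phase normalisation later
removes any residual starting-point dependence, but determinism helps
testing. Physical area is `foreground px × (2.54/dpi)²` cm².

## Elliptic Fourier shape normalisation

The forward transform computes the Kuhl–Giardina coefficients of the
closed polygon chain under arc-length parameterisation, which is the
correct choice for mask boundaries whose vertices are unevenly spaced.
The DC term uses the exact trapezoidal mean of the piecewise-linear
coordinate functions.

One subtlety deserves a record. Under arc-length parameterisation a
geometric ellipse is *not* a pure first harmonic: traversed at constant
speed, its x-coordinate approaches a triangle wave as the ellipse
flattens, so an eccentric ellipse has genuine higher-harmonic content
(about 7% third-harmonic amplitude at a 2:1 aspect ratio — confirmed
against a dense-quadrature oracle). The familiar identity "ellipse ⇒
(a₁, d₁) = (A, B), everything else 0" holds under *phase*
parameterisation (uniform parameter per vertex of a phase-sampled
polygon). `efd_forward()` therefore exposes
`parameterization = c("arc", "index")`: the pipeline always uses `"arc"`;
`"index"` exists for exactness checks and for callers whose contours are
phase-sampled. The exactness acceptance test runs under `"index"`; all
invariance tests run under the default.

Normalisation is the standard frequency-domain sequence: shift the
starting point to an end of the first-harmonic major axis (with the
π/2 correction when the half-angle formula lands on the minor axis),
rotate the plane so the major axis is horizontal, zero the DC term and
scale so the first-harmonic major *diameter* is 1000 plane units ("image
points" — distances between normalized contours are reported in these
units). Reflection is deliberately not normalised: the asymmetry metrics
need chirality. The residual 180° ambiguity of axis alignment is resolved
by a continuous, similarity-equivariant rule — the area centroid of the
reconstructed outline is placed at non-positive x (tip pointing right).
For front–back symmetric shapes (circles, ellipses) the two candidates
coincide, so the rule is vacuous exactly where it is unidentifiable; a
circular first harmonic logs a warning. The applied scale, both angles
and the flip flag are stored in the `norm` record.

K = 50 harmonics are kept (exposed as a setting), and the inverse
transform samples n = 1000 points at uniform parameter values, so point k
of any two normalized shapes corresponds to the same phase. n matches the
1000-point diameter so that per-point distances are in image points.

## Metrics

* `relative_area_difference(A1, A2) = 2|A1−A2|/(A1+A2)` — unitless,
  in [0, 2), symmetric; printed ×100.
* `contour_distances()` — for each sample point of each contour, the
  distance to the nearest point *on the polyline* of the other contour
  (symmetric, Hausdorff-style). Nearest-point pairing (rather than
  index-matched) is the default because a mirrored contour traverses in
  the reverse direction and the distance definition treats the other
  contour as a point set; the index-matched variant is available via
  `pairing = "index"`. `d_avg` is the mean and `d_max` the maximum of the
  pooled per-point distances; the histogram (default bin width 10 image
  points, configurable) bins the same values.
* `efd_distance()` — mean over the first K harmonics of the summed
  squared coefficient differences. With the 1000-point size convention
  the numbers are much larger than they would be under a unit-semi-axis
  convention; only ratios of D² across pair categories are compared, so
  the convention cancels.
* `mirror_shape()` flips y (contour and c/d coefficient rows);
  `symmetry_error_distance()` is the mean nearest-point distance from the
  mirrored samples to the original polyline; `symmetry_error_area()`
  rasterises both filled outlines on a grid that is *exactly* symmetric
  about the axis (so a symmetric shape XORs to zero regardless of grid
  step) and reports XOR count / original count. Rasterisation was chosen
  over exact polygon clipping because serrated outlines produce frequent
  near-tangencies; the estimator's grid convergence (< 1% change when the
  default 2048-cell grid is doubled) is part of the acceptance suite, and
  grids below 256 cells are rejected.
* `population_ratios()` — δ_avg, δ_max, δ_EFD contrast control–control
  pairs against control–touched pairs; δ_d, δ_a contrast touched against
  control symmetry errors.

## Statistics

`compare_groups()` screens each sample with Shapiro–Wilk at α; if both
pass, a two-tailed Welch t-test (unequal variances) compares locations,
otherwise Mann–Whitney. Degenerate samples (all values identical) fall
through to Mann–Whitney with a note. A `force_test` override reproduces
fixed per-variable choices. `build_summary()` runs the battery: per-node
area comparisons, pooled and per-node symmetry-error comparisons, and
cc-vs-ct comparisons of d_avg, d_max and D²; SD accompanies every mean
(SE is also emitted for error-bar-style outputs). No multiple-testing
correction is applied by default, matching common practice in this kind
of morphometric screen.

Pairing follows the paired-node design: a *ct* pair joins a touched leaf
with the control leaf at the corresponding node and leaf position of the
matched replicate plant (14 per node at full size); a *cc* pair joins the
two leaves attached to the same node of the same control plant (7 per
node), which estimates natural variation with no free pairing choices.

## The synthetic world

The generator states one fixed world; its defaults are not tuned to test
outcomes.

* Design: 7 plants × 2 treatments × 3 nodes (a–c) × 2 leaves = 84 scans;
  per-node control mean areas 4.67 / 22.61 / 23.96 cm² and touched-area
  factors 0.86 / 0.29 / 0.43 follow the reference measurements; scans
  default to 1200 dpi with additive Gaussian intensity noise (sd 5).
* Blade: an ovate, acute-tipped outline defined directly by low-order
  EFD coefficients (so ground truth lives in the measurement basis), a
  marginal tooth ripple at harmonic 18 (`serration_depth`, even in the
  phase, hence symmetric), and per-leaf "natural variation" as seeded
  jitter of the symmetric coefficients, with per-harmonic scales that
  shrink for higher harmonics.
* Asymmetry: an antisymmetric normal-displacement field
  `m · Σ_{j=1..4} w_j sin(jt)` (odd about the tip-to-base axis, random
  unit-RMS direction w per leaf), so mirror error grows monotonically
  with the magnitude m. Per-leaf magnitudes are log-normal
  (mean `base_asymmetry`, CV `asym_cv`); touched means are multiplied by
  `asymmetry_factor`.
* Calibration of `base_asymmetry = 0.015` (CV 0.3): the mirror-distance
  response e_d(m) is linear through the origin only for small m (the
  measured slope falls from ≈ 719 to ≈ 670 image points per unit
  magnitude between m = 0.0025 and m = 0.04, a nearest-point shortcut
  effect), so the default sits in the near-linear regime where scaling
  magnitudes by the asymmetry factor scales the *expected* symmetry-error
  ratio by the same factor, as the design contract requires. Control
  leaves then show e_d ≈ 11 image points and ε_a ≈ 7%.
* Determinism: every per-leaf stream is derived from the master seed and
  a leaf counter (order-independent); rare jitter draws whose serrated
  outline would self-intersect are rejected and redrawn from a derived
  sub-seed (bounded at 12 attempts), a negligible truncation of the
  jitter distribution.
* Area draws are log-normal with the stated CV (0.45), so areas stay
  positive; log-normal parameters are chosen mean-exact.

What the generator does *not* emulate: venation, colour texture, petioles
(petiole handling is tested with a rectangular stub), JPEG artefacts,
plant-level random effects (leaves are independent draws), and
scanner-specific noise structure. A green test therefore establishes that
the chain recovers known geometric/statistical structure from clean
scan-like rasters — not that it is robust to every artefact of real
scanner data.

## Numerical choices and degenerate inputs

* Otsu requires ≥ 2 distinct intensity levels; constant images raise a
  degenerate-histogram error. The dark class is `value ≤ threshold`.
* Empty masks, exclusions that erase the whole blade, and masks whose
  largest component is below the speck threshold raise "no leaf found".
* Contours need ≥ 3 distinct vertices and nonzero perimeter; zero-length
  edges are dropped before the transform.
* The ε_a estimator's denominator is the rasterised original-blade count,
  keeping numerator and denominator on the same grid.
* Distance computations are exact point-to-segment distances in C++ (no
  spatial indexing; n = 1000 keeps the quadratic cost at ~10⁶ cheap
  operations per pair).
* Identical constant samples give p = 1 (not significant) in the test
  battery; Welch on identical samples yields statistic 0.

## Known limitations

* Physical-area accuracy is quantisation-limited: below ≈ 150 dpi a
  cm-scale object's raster area differs from its true area by more than
  1% no matter the estimator, so the calibration guarantee is stated for
  ≥ 150 dpi.
* The crack contour of a component with diagonal-only pixel contacts can
  touch itself at a corner; smooth blade masks at working resolutions do
  not produce this, and the EFD stage is insensitive to point contacts.
* δ_avg/δ_max/δ_EFD in the synthetic world sit closer to 1 than the
  reference study reported, because the generator induces contour change
  in touched leaves only through the asymmetry field; a dedicated
  "contour effect" knob was deliberately not added (the design exposes
  only area and asymmetry effects).
* Only PGM/PPM raster input is supported in this build (no JPEG/PNG
  decoder dependency); scans in other formats must be converted
  losslessly beforehand.
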