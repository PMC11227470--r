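# leafmorph

Outline-based morphometrics of scanned leaves for touch-stress
(thigmomorphogenesis) phenotyping.

Plants that are repeatedly touched during growth change their leaf
morphology: blades stay smaller, contours deform, and bilateral (axial)
symmetry degrades. `leafmorph` implements the full measurement chain needed
to quantify these effects from flatbed scans of detached leaves:

1. **Mask extraction** — RGB scan → BT.601 luminance → Otsu binarisation →
   morphological cleaning (hole filling, largest-component selection) →
   optional petiole exclusion → crack-edge contour tracing and physical
   area calibration (`px * (2.54/dpi)^2` cm²).
2. **Shape normalisation** — Kuhl–Giardina elliptic Fourier descriptors
   (EFD): for a closed contour, harmonic *i* contributes a quadruple
   (aᵢ, bᵢ, cᵢ, dᵢ) of
   x(t) = A₀ + Σᵢ aᵢ cos(iωt) + bᵢ sin(iωt) (y analogous with cᵢ, dᵢ).
   Frequency-domain normalisation removes position, scale, rotation and
   starting point; the first-harmonic ellipse major diameter is scaled to
   1000 "image points" and the major axis becomes the horizontal symmetry
   axis. K = 50 harmonics are kept; the inverse transform resamples each
   outline at n = 1000 phase-aligned points.
3. **Shape and asymmetry metrics** —
   * relative area difference of a pair: δₐ = 2|A₁−A₂|/(A₁+A₂);
   * contour distances d_avg / d_max (symmetric nearest-point-on-polyline,
     i.e. Hausdorff-style) with per-point distance histograms;
   * EFD-space distance D² = (1/K) Σᵢ Σ (Δa² + Δb² + Δc² + Δd²);
   * axial-symmetry errors: e_d = mean distance between an outline and its
     mirror image about the symmetry axis, and ε_a = mismatch (XOR) area
     between the blade and its mirror, relative to blade area;
   * population ratios δ_avg, δ_max, δ_EFD (control–control pairs vs
     control–touched pairs) and δ_d, δ_a (touched vs control symmetry).
4. **Inference** — Shapiro–Wilk normality screening per sample, then
   Welch's t (both normal) or Mann–Whitney, at α = 0.05, for areas,
   symmetry errors, and pair metrics.
5. **Synthetic studies** — a generator that emulates the reference design
   (7 plants × 2 treatments × 3 nodes × 2 leaves = 84 scans) with an
   ovate, serrated, nettle-like blade defined in EFD space and an
   antisymmetric normal-displacement field as asymmetry ground truth, so
   the whole chain is testable without any deposited scan data.

## Worked example

Simulate a full 84-leaf study with the reference effect sizes (per-node
area reduction, 1.6× asymmetry increase) and summarise it:

```r
library(leafmorph)
design <- study_design(master_seed = 42L, dpi = 300)
sim    <- simulate_study_measurements(design, K = 50, n = 500,
                                      grid_resolution = 1024)
summ   <- build_summary(sim$measurements, sim$pairs)
print(summ)
```

```
Per-leaf summary (mean ± SD):
  node a control  n=14  area   5.28 ±  4.31 cm2  e_d  11.03 ±  5.13  eps_a   6.5% ±  3.1
  node b control  n=14  area  21.01 ±  7.85 cm2  e_d  10.74 ±  3.10  eps_a   6.4% ±  2.0
  node c control  n=14  area  25.89 ±  7.13 cm2  e_d  12.90 ±  5.84  eps_a   7.8% ±  3.6
  node a touched  n=14  area   4.17 ±  1.44 cm2  e_d  17.52 ±  7.38  eps_a  10.7% ±  4.4
  node b touched  n=14  area   8.30 ±  6.83 cm2  e_d  16.53 ±  5.42  eps_a  10.1% ±  3.3
  node c touched  n=14  area   9.06 ±  4.86 cm2  e_d  17.02 ±  7.02  eps_a  10.3% ±  4.3
Pairwise summary:
  node a cc  n= 7  delta_area  56.0%  d_avg   17.8  d_max   42.8  D2 22.3338
  node b cc  n= 7  delta_area  36.3%  d_avg   11.4  d_max   30.2  D2 9.3801
  node c cc  n= 7  delta_area  26.0%  d_avg   15.1  d_max   38.4  D2 17.1502
  node a ct  n=14  delta_area  46.3%  d_avg   19.4  d_max   47.8  D2 26.2772
  node b ct  n=14  delta_area 100.7%  d_avg   13.8  d_max   34.4  D2 14.5387
  node c ct  n=14  delta_area  98.1%  d_avg   14.0  d_max   37.5  D2 14.8513
Ratios: delta_avg=0.940 delta_max=0.931 delta_EFD=0.937 delta_d=1.473 delta_a=1.499
Tests: 8 of 14 significant at alpha=0.05
```

Reading the output: touched leaves at the lower nodes (b, c) lose most of
their blade area (means ≈ 8–9 vs ≈ 21–26 cm² in controls) while node *a*
shows no real effect; both symmetry errors are ≈ 1.5× larger in the
touched group (`delta_d`, `delta_a` estimate the injected 1.6× factor);
`e_d` and `d_avg`/`d_max` are in normalized "image points" (major diameter
= 1000), `eps_a` and `delta_area` are printed as percentages.

The same chain runs on scan files from disk:

```r
mask  <- preprocess_leaf("scan_042.ppm", dpi = 1200)   # Otsu + cleaning
m     <- measure_leaf_image("scan_042.ppm", dpi = 1200)
m$area_cm2; m$e_d; m$epsilon_a
```

## Command line

```sh
inst/exec/leafmorph generate --out study/      --seed 1 --dpi 300
inst/exec/leafmorph measure  --images study/   --manifest study/manifest.csv --out meas/
inst/exec/leafmorph compare  --measurements meas/measurements.csv --out report/
```

`compare` writes `pairs.csv`, Table-style `summary_leaves.csv` /
`summary_pairs.csv`, the test battery `tests.csv` and the five ratio
statistics in `ratios.json`; every output directory carries the
serialised `run_config.json`.

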