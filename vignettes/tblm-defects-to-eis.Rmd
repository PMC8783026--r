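---
title: "From AFM defect maps to impedance spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From AFM defect maps to impedance spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbleis)
```

## The problem

Tethered bilayer lipid membranes (tBLMs) on gold electrodes are a standard
platform for measuring the activity of pore-forming toxins. A toxin pore is
a conductive defect: ions enter through it into the thin aqueous reservoir
between bilayer and metal, spread laterally, and charge the interfacial
(Helmholtz) capacitance. Electrochemical impedance spectroscopy (EIS) sees
this as a characteristic dip of the admittance phase `arg Y` at a frequency
`f_min` that grows with defect density; atomic force microscopy (AFM) sees
the individual pores as pits and yields their coordinates.

`tbleis` connects the two measurements. It provides

* containers and statistics for defect coordinate sets, including a
  Voronoi-based clustering statistic;
* object-detection-style scoring (IoU matching, precision/recall/F1 and the
  density ratio Q_N) of predicted against annotated defect positions;
* a generator of synthetic "detector outputs" of controlled accuracy;
* a finite-element forward model that predicts the complex admittance
  spectrum of an arbitrary defect map;
* a grid search that recovers physical membrane parameters by matching the
  modeled phase minimum to a reference spectrum.

Everything runs on synthetic data generated inside the package, so the full
workflow in `analysis/` is reproducible without measured inputs.

## Defect sets and the clustering statistic

A `defect_set()` holds defect centers in nanometers on a rectangular field
(image convention: origin top-left, y downward; 2 um scans at 512 x 512
pixels give 3.90625 nm/px). Detection boxes are equalized to 50 nm squares
(`r_box = 25`), the convention under which all IoU scores are computed.

Clustering is summarized by `voronoi_sigma()`: the Voronoi tessellation of
the defect centers is computed (via `deldir`), every cell is clipped to the
field rectangle, cell areas are normalized by multiplying with the defect
density `N_def`, and sigma is the standard deviation of these normalized
areas. A perfect lattice gives 0; homogeneous Poisson patterns give about
0.53-0.55 (the cell-area variability of the Poisson-Voronoi tessellation,
slightly raised by boundary clipping); the clustered patterns typical of
toxin-damaged membranes give 0.8-1.3. Clipping unbounded edge cells to the
field keeps all areas finite and makes them sum exactly to the field area,
which the test suite asserts to 1e-6 relative tolerance. Sigma is computed
on the full coordinate set of a field rather than per scan fragment;
fragment-wise averaging would mix in stitching artefacts without changing
the ranking of patterns.

Duplicate coordinates are rejected (degenerate tessellation, and in
practice a symptom of corrupt input) rather than merged.

## Scoring detector output

`match_defects()` pairs predicted with true defects one-to-one. Candidate
pairs must exceed IoU 0.5 (strictly); candidates are consumed greedily in
order of ascending center distance, with ties broken toward the lower
predicted index. For 50 nm boxes, IoU > 0.5 corresponds to a center offset
of at most about 17 nm, so the pairing is effectively local and the greedy
assignment almost always attains the maximum matching (the suite checks
>= 95% agreement with an exhaustive matcher on small sets). Precision,
recall and F1 follow the usual definitions; `Q_N` is the predicted-to-true
density ratio, which matters because the spectral features respond to
defect density more than to exact positions.

## Synthetic degradation of detector accuracy

To study how detection errors propagate into spectra one needs many
detector outputs of graded accuracy. `degrade_set()` emulates them from a
ground-truth set:

1. every defect is jittered by independent N(0, s^2) draws per coordinate
   (s = 4 nm by default);
2. `n_remove` defects are deleted, each the nearest not-yet-removed defect
   to a fresh draw from a Gaussian KDE (bandwidth 400 nm) fitted on the
   true coordinates — false negatives that respect the cluster layout;
3. `n_add` defects are inserted at KDE draws — false positives in
   plausible places.

Units deserve a note: s and the bandwidth are nanometers. With s = 4 nm
the jitter shifts a 50 nm box by well under the ~17 nm IoU break-point, so
jitter alone leaves precision and recall at 1 — which is what makes the
upper end of the accuracy range reachable at all. A pixel-unit reading
(4 px = 15.6 nm) would cap the attainable IoU near the threshold and
contradict the achievable precision/recall ranges. KDE draws landing
outside the field are rejection-resampled; removal targets are drawn
without replacement.

`case_grid()` steps `n_remove` and `n_add` from 0 in increments of
`round(0.03 N)` while strictly below `floor(N/2)` and takes the Cartesian
product: 324 cases for N = 172, 256 for N = 158 and for N = 97.
`generate_batch()` runs and scores the whole grid reproducibly from one
seed. At the heaviest corner (half the defects removed, as many added) the
precision floor is `(N - n_remove)/N`, about 0.54 for N = 97.

## The electrochemical forward model

The 3D electrochemistry is reduced to a 2D thin-film problem for the
complex amplitude `u(x, y)` of the submembrane reservoir potential at
angular frequency `w = 2 pi f`:

    g_s lap(u) - i w (C_H + C_m) u = - i w C_m U0

with `g_s = d_sub / rho_sub` the sheet conductance of the reservoir
(thickness `d_sub`, specific resistance `rho_sub`), `C_m` the membrane and
`C_H` the Helmholtz capacitance per area. Defects are ideal pores: on each
rim disk of radius `r_def` the potential is clamped to the drive, `u = U0`
(zero internal pore resistance). The outer boundary of the scanned patch
carries zero normal flux — the simplest defensible closure for a finite
patch; no periodic images are assumed. The reported observable is the
area-normalized admittance

    Y(w) = i w C_H <u> / U0,

the patch average `<u>` counting defect interiors at `U0`. With no defects
`u` is uniform and `Y = i w C_m C_H / (C_m + C_H)`: a pure capacitor with
phase 90 degrees, which the implementation returns exactly. Bulk
electrolyte series resistance is omitted, so the phase also returns to 90
degrees at high frequency; a series element can be added externally by the
usual impedance composition if needed.

Defaults are literature-typical tBLM values, all overridable:
`C_m = 0.8 uF/cm^2`, `C_H = 9 uF/cm^2`, `d_sub = 1.5 nm`, and
`rho_sub = 10^4.5 Ohm cm` as the customary prior value. The drive
amplitude cancels (the system is linear); it is kept explicit only for
clarity.

### Discretization

The solver uses P1 triangles on an unstructured mesh built from a graded
point cloud: each defect carries concentric vertex rings whose radial
spacing grows geometrically from the rim, embedded in a jittered
quasi-uniform background; Delaunay triangulation (`deldir`) connects the
cloud, triangles inside defect disks are removed, and rim vertices sit at
an area-matched radius so the rim polygon encloses exactly `pi r_def^2`
(removing the leading geometric error of the Dirichlet rim). One complex
sparse system per frequency is solved as the equivalent 2n-real block
system with `Matrix`'s sparse LU.

The dominant error is the angular resolution at the rim. With 96 rim
points and growth factor 1.15 the solver agrees with the semi-analytic
radial solution to 0.35% in |Y| and 0.1 degrees in phase across
0.1-1e5 Hz; the default (48 rim points) is a few percent, and the coarse
settings used for multi-spectrum studies (20-24 rim points) bias `f_min`
by up to ~7% — a bias that cancels almost entirely in the true-vs-predicted
*differences* the studies report, and exactly in self-generated fit
references. Defect disks must be pairwise disjoint; overlapping disks are
a geometry error (the grid fit flags such combinations instead of
aborting). Disks touching the patch boundary are clipped.

### The radial verification oracle

For a single centered defect in a circular patch the same problem has a
closed form in modified Bessel functions of complex argument
(`radial_spectrum()`), with the admittance integral done analytically.
Because base R's Bessel functions are real-only, the package implements
exponentially scaled complex `I0, I1, K0, K1` (power series below |z| = 10
for K and 25 for I, large-argument asymptotics above, all scaled to avoid
overflow at large |z|); they are validated against base R on the real axis
and the whole solution against an independent 6000-node finite-difference
solve to < 0.1 degrees. This chain — series/asymptotics vs. dense FD vs.
2D FEM — is the package's accuracy argument for the solver.

### Spectral features

`spectral_features()` locates the interior minimum of the phase on the
(log10 f, phase) plane and refines the discrete argmin with a three-point
parabola, so features are sub-grid accurate (doubling the frequency-grid
density moves log10 f_min by < 0.01). Spectra whose phase minimum sits at
a grid endpoint (e.g. the zero-defect capacitor) raise an error rather
than returning a fake feature. `compare_spectra()` reports
`delta_f_log = log10 f_min(true) - log10 f_min(pred)` and the phase
difference at the minima.

A property worth knowing when interpreting results: `f_min` scales
*slightly superlinearly* with defect density. The radial closed form gives
a doubling shift of -0.33 decades at any dilute density (not exactly
-log10 2 = -0.301) because the cell-size-to-defect-radius ratio enters
logarithmically; dilute 2D random patterns measure about -0.31 to -0.36
depending on the realization (10-seed paired measurements). The
leading-order "f_min proportional to density" intuition is good to about
15%.

## Grid-search parameter recovery

`fit_membrane_params()` scans the default 7 x 11 grid (r_def = 1-13 nm in
2 nm steps; log10 rho_sub = 4.0-5.0 in 0.1 steps; 77 combinations),
models the defect set at each point (meshing once per radius — the mesh
does not depend on rho_sub), and scores

    l1 = |delta log10 f_min| + |delta arg Y_min| / 90.

The mixed decade/degree norm has no canonical weighting; dividing the
phase term by 90 degrees makes both terms O(1) over the physically
relevant range, and the weight is an explicit argument. Ties break toward
smaller rho exponent, then smaller radius. Self-generated on-grid
references are recovered exactly (the discretization bias cancels);
against noisy references rho_sub is pinned far more tightly than r_def,
whose influence on the phase minimum is weak over the 1-13 nm range — the
fit table's l1 valley is long in r and narrow in rho.

## Synthetic data: what it does and does not emulate

The generators exist so the pipeline can be exercised end to end at known
ground truth.

* **Point patterns** — homogeneous Poisson, and Thomas (Neyman-Scott)
  cluster processes for VLY-like clustered damage. The three
  `surface_preset()`s were calibrated once, by matching the Voronoi sigma
  statistic (not any insertion mechanism), to the density/sigma regimes of
  the three annotated 4 um test patches: densities 10.75/6.06/9.88 um^-2
  with sigma about 1.2/1.0/0.9. An optional hard-core thinning keeps
  defect disks disjoint when a pattern feeds the FEM solver.
* **Topography images** — flat background + correlated roughness
  (0.10 nm rms, 10 nm correlation) + per-scan-line offsets (0.05 nm) -
  Gaussian pits (2 nm deep, 10 nm radius) at the defect positions,
  16-bit TIFF exportable. These are lookalikes for detector testing; tip
  convolution, stitching artefacts and instrument drift are deliberately
  out of scope, so detector scores on them bound real-image performance
  from above.
* **Blob detector** — multi-scale Laplacian-of-Gaussian pit detection with
  non-maximum suppression, a classical stand-in for a learned detector.
  Its threshold (0.7 nm in scale-normalized response, against a 1 nm
  response for a nominal pit) was calibrated so pure-noise images yield
  at most ~2 false positives per field while noiseless renderings are
  detected perfectly. As with real detectors, recall drops markedly inside
  clusters, where pits merge.
* **Reference spectra** — forward-model output with independent Gaussian
  phase noise per frequency at constant modulus, standing in for measured
  EIS data in fit studies.

Passing tests on these generators therefore demonstrate correctness of the
algorithms and the claimed sensitivities, not detector performance on real
AFM scans or quantitative agreement with any specific instrument.

## Numerical choices and problem sizes

Study scripts and tests run at deliberately reduced scale so the whole
suite executes in minutes on one core: study surfaces of 10-100 defects on
1.2-2.8 um fields, frequency grids of 3-5 points per decade (the parabolic
refinement keeps feature resolution well below the grid spacing), and
coarse mesh settings for multi-spectrum batches. The full 4 um, 61-
frequency, fine-mesh configuration is available through the same
arguments; only solver time changes. All stochastic stages take explicit
seeds and are bit-reproducible; batch generators derive per-case seeds
from a single master seed.

## Known limitations

* The thin-film reduction ignores the finite conductance of the pore
  channel itself and any potential variation across the reservoir
  thickness; both are good approximations for nanometer reservoirs but
  bias absolute spectra for large or long pores.
* No bulk series resistance by default: measured spectra showing a
  high-frequency phase roll-off need that element added before features
  are compared.
* Overlapping defect disks (possible in heavily degraded synthetic sets at
  large r_def) are treated as infeasible rather than merged.
* The Voronoi statistic is computed on the full field; values for very
  small N (< ~20) are noisy, and patterns with duplicate coordinates are
  rejected.
* Coarse meshes bias absolute `f_min` upward by a few percent; use fine
  settings (96 rim points) when absolute feature values, not differences,
  are the target.
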