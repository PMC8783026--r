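# tbleis

Predicting electrochemical impedance spectra of tethered bilayer lipid
membranes (tBLMs) from AFM-derived defect maps — and recovering physical
membrane parameters from the comparison.

## What problem this solves

When a pore-forming toxin (such as vaginolysin) attacks a tBLM, each pore
is a conductive defect connecting the bathing solution to the thin aqueous
reservoir between the bilayer and the gold support. Two measurements see
this damage from different sides:

* **AFM** resolves the individual pores as pits and yields defect
  coordinates, densities `N_def` and their spatial clustering;
* **EIS** integrates their electrical effect: the admittance phase
  `arg Y(f)` develops a minimum whose position `(f_min, arg Y_min)` encodes
  defect density, defect radius `r_def`, and the specific resistance
  `rho_sub` of the submembrane reservoir.

`tbleis` implements the bridge between the two, for biophysicists and
biosensor developers working with supported membranes:

1. **Defect-set statistics** — field-clipped Voronoi tessellation and the
   clustering statistic `sigma = sd(cell areas x N_def)` (lattice 0,
   Poisson ~0.53, clustered damage 0.8–1.3).
2. **Detection scoring** — one-to-one IoU matching (50 nm equalized boxes,
   threshold 0.5) giving precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
   `F1 = 2PR/(P+R)` and the density ratio `Q_N = N_def^pred / N_def^true`.
3. **Degradation simulation** — synthetic detector outputs of controlled
   accuracy: coordinate jitter `N(0, 4^2 nm)` plus KDE-guided removals and
   additions stepping by 3% of N up to N/2 (324 cases for N = 172).
4. **Forward EIS model** — P1 finite elements for the submembrane
   thin-film equation
   `g_s lap(u) - iw(C_H + C_m) u = -iw C_m U0`, `u = U0` on defect rims,
   zero flux on the patch boundary; admittance `Y = iw C_H <u> / U0`.
   Verified against a semi-analytic radial Bessel solution to 0.35% / 0.1°.
5. **Parameter fitting** — grid search over `r_def = 1..13 nm` and
   `rho_sub = 10^4.0..10^5.0 Ohm cm` (77 combinations) minimizing
   `|d log10 f_min| + |d arg Y_min|/90` against a reference spectrum.
6. **Synthetic data** — clustered point patterns (Thomas process), AFM-like
   topography rendering, a classical LoG blob detector, and noisy reference
   spectra, so the entire pipeline runs without measured data.

## Worked example

```r
library(tbleis)

# a clustered 4 x 4 um surface in the regime of a VLY-damaged tBLM
s <- sample_point_process(surface_preset(1, seed = 20260102))
s
#> <defect_set 'thomas': 163 defects on 4000 x 4000 nm field, 10.2 um^-2>
round(voronoi_sigma(s), 2)
#> [1] 1.03

# degrade it into a plausible "detector output" and score it
d <- degrade_set(s, degradation_params(n_remove = 25, n_add = 25, seed = 7))
accuracy_metrics(match_defects(s, d), s, d)
#> <accuracy_metrics: precision 0.840, recall 0.840, F1 0.840, Q_N 1.000>

# model both spectra and compare their phase minima (~3 min on one core)
mp  <- membrane_params(r_def = 3)          # rho_sub = 10^4.5 Ohm cm default
fg  <- frequency_grid(1, 1e4, 5)
ctrl <- mesh_control(rim_points = 24, grade = 1.4, grade_growth = 0.15,
                     h_far_frac = 1/20)
compare_spectra(model_spectrum(s, mp, fg, ctrl),
                model_spectrum(d, mp, fg, ctrl))
#> <spectrum_delta: delta f_log -0.0583 dec, delta argY +0.950 deg>
```

A detector output with F1 = 0.84 shifts the phase minimum by 0.06 decades
(about −13% in f_min) and the phase value by under a degree: because the
density ratio stays at Q_N = 1.00, the spectral features — which respond
to defect density far more than to exact positions — remain close, and
that is what makes EIS prediction from imperfect detections viable.

The numbered scripts in `analysis/` run the full workflow and write tables
under `results/`: surface generation (`01`), blob-detector benchmarking on
rendered topographies (`02`), full degradation batches — e.g. precision
spanning 0.54–1.00 over 196 cases on the sparse clustered surface (`03`),
detection accuracy versus spectral deviation (`04`), and side-by-side
parameter recovery for true and degraded defect sets (`05`).

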