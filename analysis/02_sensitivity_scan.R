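#!/usr/bin/env Rscript
# Sensitivity of adaptive therapy to the PSA production weights: TCR over
# the (alpha, beta) simplex at step 0.05 for each patient category (the
# heatmap grids). Writes results/scan_<category>.csv and PNG heatmaps.

suppressPackageStartupMessages(library(psadapt))

outdir <- "results"
dir.create(file.path(outdir, "figures"), recursive = TRUE, showWarnings = FALSE)
step <- 0.05

for (cat in c("best_responder", "responder", "non_responder")) {
  scan <- alpha_beta_scan(representative_patient(cat), step = step)
  write_table_csv(scan, file.path(outdir, sprintf("scan_%s.csv", cat)))

  app <- scan[scan$at_applicable, ]
  message(sprintf(
    "%s: MTD TCR %.0f; AT applicable at %d/%d grid points; AT TCR range %s",
    cat, scan$tcr_mtd[1], nrow(app), nrow(scan),
    if (nrow(app)) sprintf("[%.0f, %.0f]", min(app$tcr_at), max(app$tcr_at))
    else "-"))
  stopifnot(all(app$tcr_at >= app$tcr_mtd))

  # lower-triangular heatmap of TCR(AT); MTD value where AT not applicable
  vals <- sort(unique(scan$alpha))
  z <- matrix(NA_real_, length(vals), length(vals))
  for (i in seq_len(nrow(scan))) {
    z[match(scan$alpha[i], vals), match(scan$beta[i], vals)] <-
      if (scan$at_applicable[i]) scan$tcr_at[i] else scan$tcr_mtd[i]
  }
  grDevices::png(file.path(outdir, "figures", sprintf("heatmap_%s.png", cat)),
                 width = 900, height = 800, res = 120)
  graphics::image(vals, vals, z, col = grDevices::hcl.colors(50, "viridis"),
                  xlab = expression(alpha ~ "(T+ PSA weight)"),
                  ylab = expression(beta ~ "(TP PSA weight)"),
                  main = sprintf("Time to competitive release, %s",
                                 gsub("_", " ", cat)))
  grDevices::dev.off()
}

message("written: ", outdir, "/scan_*.csv and ", outdir, "/figures/heatmap_*.png")
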