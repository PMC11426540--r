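#!/usr/bin/env Rscript
# Representative patients: compare continuous maximum tolerable dose (MTD)
# with PSA-guided adaptive therapy (AT) for the three response categories,
# under the four standard assumptions about which cell types produce PSA.
# Writes results/comparison.csv and exemplar trajectory exports.

suppressPackageStartupMessages(library(psadapt))

outdir <- "results"
dir.create(file.path(outdir, "trajectories"), recursive = TRUE,
           showWarnings = FALSE)

categories <- c("best_responder", "responder", "non_responder")

message("Time to competitive release (TCR), MTD vs adaptive therapy")
tables <- lapply(categories, function(cat) {
  tab <- comparison_table(representative_patient(cat), sample_dt = 10)
  message("\n== ", cat, " ==")
  for (i in seq_len(nrow(tab))) {
    message(sprintf(
      "  alpha=%.2f beta=%.2f  MTD %4.0f  AT %s  improvement %s",
      tab$alpha[i], tab$beta[i], tab$tcr_mtd[i],
      if (is.na(tab$tcr_at[i])) "  N/A (never discontinued)"
      else sprintf("%4.0f", tab$tcr_at[i]),
      if (is.na(tab$pct_improvement[i])) "N/A"
      else sprintf("%.0f%%", tab$pct_improvement[i])))
  }
  tab
})
comparison <- do.call(rbind, tables)
write_table_csv(comparison, file.path(outdir, "comparison.csv"))

# exemplar full trajectories (the time-course panels): MTD plus the most
# favourable applicable AT setting per category
exemplars <- list(best_responder = c(1, 0), responder = c(0, 1),
                  non_responder = c(0, 1))
for (cat in categories) {
  pat <- representative_patient(cat)
  w <- psa_weights(exemplars[[cat]][1], exemplars[[cat]][2])
  for (proto in c("MTD", "AT")) {
    sim <- run_simulation(pat$params, pat$init, proto, w, sample_dt = 1)
    write_trajectory(sim, file.path(outdir, "trajectories",
                                    sprintf("%s_%s.csv", cat, tolower(proto))))
  }
}

message("\nAdaptive therapy never shortened TCR where it was applicable: ",
        all(comparison$tcr_at >= comparison$tcr_mtd, na.rm = TRUE))
message("written: ", file.path(outdir, "comparison.csv"),
        " and ", file.path(outdir, "trajectories"), "/")
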