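#!/usr/bin/env Rscript
# Stage 1b: per-trial spatial analysis. Accessions and replicates are fixed
# effects; the residual is a separable AR1(row) x AR1(col) field estimated by
# profiled REML. Produces accession BLUEs per site for grain yield and plant
# height, the two traits carried through the prediction stages.

suppressMessages(library(gsresp))
dir.create("results", showWarnings = FALSE)

trial <- read_table_csv("results/data/plots.csv", class_out = "trial_table")
traits <- c("GY", "PH")

blues <- list(); fits <- list()
for (s in unique(trial$site)) {
  for (tr in traits) {
    f <- fit_trial_blues(trial[trial$site == s, ], tr, grid_step = 0.1)
    blues[[paste(s, tr)]] <- f$blues
    fits[[paste(s, tr)]] <- f$fit
    message(sprintf("%s / %s: rho_row %.2f, rho_col %.2f, sigma2 %.3f",
                    s, tr, f$fit$rho_row, f$fit$rho_col, f$fit$sigma2_spatial))
  }
}
blues <- do.call(rbind, blues)
write_table_csv(blues, "results/blues_stage1.csv")
write_components_json(fits, "results/spatial_fits.json")
message(sprintf("wrote %d BLUEs across %d site-trait combinations",
                nrow(blues), length(fits)))
message("note: the generator's AR1 autocorrelations are 0.4 in both directions; ")
message("row/column random effects are absorbed into the fitted correlations here")
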