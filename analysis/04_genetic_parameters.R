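#!/usr/bin/env Rscript
# Stage 2: genomic variance components. For each site, every pair of traits
# is fitted with the bivariate GBLUP model; a trait's additive and residual
# variances (and hence its narrow-sense heritability) are reported as the
# average over its seven pairwise fits, which stabilizes the per-fit REML
# noise considerably. Genetic correlations come from the same fits.

suppressMessages(library(gsresp))
dir.create("results", showWarnings = FALSE)

blues <- read_table_csv("results/data/blues_simulated.csv", class_out = "blue_table")
grm <- read_grm_tsv("results/grm.tsv")
traits <- unique(blues$trait)
sites <- unique(blues$site)

h2_rows <- list(); cor_rows <- list()
for (s in sites) {
  acc_A <- acc_E <- matrix(0, length(traits), length(traits),
                           dimnames = list(traits, traits))
  for (i in seq_along(traits)) for (j in seq_len(i - 1)) {
    f <- fit_multitrait(blues, grm, traits = c(traits[i], traits[j]), site = s)
    Tm <- f$components$T; Rm <- f$components$Rres
    acc_A[i, i] <- acc_A[i, i] + Tm[1, 1]; acc_A[j, j] <- acc_A[j, j] + Tm[2, 2]
    acc_E[i, i] <- acc_E[i, i] + Rm[1, 1]; acc_E[j, j] <- acc_E[j, j] + Rm[2, 2]
    cor_rows[[paste(s, i, j)]] <- data.frame(
      site = s, trait_x = traits[i], trait_y = traits[j],
      r_A = f$correlations$r_A, r_P = f$correlations$r_P)
  }
  n_pair <- length(traits) - 1
  h2_rows[[s]] <- data.frame(
    site = s, trait = traits,
    sigma2_A = diag(acc_A) / n_pair, sigma2_e = diag(acc_E) / n_pair,
    h2 = heritability(diag(acc_A) / n_pair, diag(acc_E) / n_pair))
}
h2tab <- do.call(rbind, h2_rows)
cortab <- do.call(rbind, cor_rows)
write_table_csv(h2tab, "results/heritability.csv")
write_table_csv(cortab, "results/genetic_correlations.csv")

message("narrow-sense heritability (averaged over 7 pairwise bivariate fits):")
print(round(with(h2tab, tapply(h2, list(trait, site), identity)), 2))
message("additive genetic correlations with grain yield:")
gy <- cortab[cortab$trait_x == "GY" | cortab$trait_y == "GY", ]
gy$other <- ifelse(gy$trait_x == "GY", gy$trait_y, gy$trait_x)
print(round(with(gy, tapply(r_A, list(other, site), identity)), 2))
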