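#!/usr/bin/env Rscript
# Stage 0: generate the synthetic study — 349 accessions x 6,911 SNPs, eight
# agronomic traits, four environments with replicated row-column trials —
# and write every artifact downstream stages read.

suppressMessages(library(gsresp))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

params <- default_sim_params(seed = 20170349L)
print(params)

geno <- simulate_genotypes(params)
print(geno)
effects <- simulate_true_effects(geno, params)
trial <- simulate_trial(geno, effects, params)
blues <- simulate_blues(geno, effects, params)

write_vcf(geno, "results/data/genotypes.vcf")
write_dosage_tsv(geno, "results/data/genotypes.tsv")
write_table_csv(trial, "results/data/plots.csv")
write_table_csv(blues, "results/data/blues_simulated.csv")
write_table_csv(data.frame(accession = rownames(effects$g), effects$g),
                "results/data/true_additive_effects.csv")

message(sprintf("plots per site: %d; traits: %s",
                nrow(trial) / params$n_sites,
                paste(params$traits, collapse = ", ")))
message(sprintf("grain-yield site means (t/ha): %s",
                paste(sprintf("%.1f", params$site_means[, "GY"]), collapse = ", ")))
message("wrote genotypes (VCF + TSV), plot table, accession-level phenotypes, true effects")
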