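#!/usr/bin/env Rscript
# Generate the synthetic study datasets: a three-system proteome (reference
# primary hepatocytes vs two hepatic lines), a 3-batch x 4-replicate
# spectral-count experiment, and a 3x3 depletion/injection secretome.
# Ground truth is written alongside so later stages can score themselves.

suppressPackageStartupMessages(library(hepaquant))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
cat("Simulating proteome:", cfg$n_proteins, "proteins,",
    paste(cfg$systems, collapse = "/"), "\n")
sim <- simulate_proteome(cfg)

int_df <- data.frame(accession = sim$quant$proteins$accession,
                     mw = sim$quant$proteins$mw,
                     sim$quant$intensity, check.names = FALSE)
write_result_table(int_df, "results/simulated_intensities.tsv",
                   params = list(seed = seed))
truth_df <- data.frame(accession = rownames(sim$truth$copies),
                       sim$truth$copies,
                       fc_class = sim$truth$fc_class, check.names = FALSE)
write_result_table(truth_df, "results/simulated_truth_copies.tsv",
                   params = list(seed = seed))

counts <- simulate_counts(cfg, frac_differential = 0.05, planted_fc = 4)
cnt_df <- data.frame(accession = rownames(counts$counts), counts$counts,
                     planted = counts$truth, check.names = FALSE)
write_result_table(cnt_df, "results/simulated_counts.tsv",
                   params = list(seed = seed, batches = cfg$n_batches))

sec <- simulate_secretome(cfg)
sec_df <- data.frame(accession = rownames(sec$experiment$quant$intensity),
                     sec$experiment$quant$intensity,
                     true_rate = unname(sec$truth$rate), check.names = FALSE)
write_result_table(sec_df, "results/simulated_secretome.tsv",
                   params = list(seed = seed,
                                 protein_after_ug = sec$experiment$protein_after_ug,
                                 protein_before_ug = sec$experiment$protein_before_ug,
                                 albumin_purity = sec$experiment$albumin_purity))

cat("Wrote results/simulated_{intensities,truth_copies,counts,secretome}.tsv\n")
cat("Detected entries:", sum(!is.na(sim$quant$intensity)), "of",
    length(sim$quant$intensity), "intensity cells\n")
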