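#!/usr/bin/env Rscript
# Stage 1: generate the study cohort.
#
# Simulates the default study conditions — a 35-animal cohort (WXP n=7,
# XP n=7, EUP n=21) with 300 cohort-shared and 90 group-specific planted SVs
# over a 5-autosome + X/Y genome — and emits the raw analysis inputs: a GFF3
# gene model, per-sample call tables from two noisy callers, the sample
# sheet, gene sets, and the ground-truth table used later for validation.

suppressPackageStartupMessages(library(svcohort))

seed <- 42
base <- file.path("results", "run")
in_dir <- file.path(base, "inputs")
dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
genes <- simulate_gene_models(cfg, gff3_path = file.path(in_dir, "genes.gff3"))
truth <- simulate_cohort(cfg, genes)
write.table(truth, file.path(in_dir, "truth.tsv"), sep = "\t",
  quote = FALSE, row.names = FALSE)
sheet <- sim_sample_sheet(cfg)
write.table(sheet, file.path(in_dir, "sample_sheet.tsv"), sep = "\t",
  quote = FALSE, row.names = FALSE)
for (caller in c("callerA", "callerB")) {
  calls <- simulate_caller_output(truth, cfg, caller,
    dir = file.path(in_dir, "calls"))
  cat(sprintf("%s: %d calls across %d samples (%.1f%% false positives)\n",
    caller, nrow(calls), length(unique(calls$sample_id)),
    100 * mean(is.na(calls$truth_id))))
}
gs <- simulate_gene_sets(truth, genes, cfg)
write_gmt(gs$gene_sets, file.path(in_dir, "gene_sets.gmt"))
writeLines(gs$aging_genes, file.path(in_dir, "aging_genes.txt"))

cat(sprintf("planted %d SVs (%d shared, %d group-specific) over %d genes\n",
  nrow(truth), sum(truth$planted_as == "shared"),
  sum(truth$planted_as != "shared"), length(genes$genes)))
cat("inputs written to", in_dir, "\n")
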