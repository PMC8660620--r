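#!/usr/bin/env Rscript
# Stage 4: cohort comparisons.
#
# Builds the samples x SVs presence/absence genotype matrix, screens for
# WXP-specific SVs (carriers in WXP only), summarises the Venn partition and
# chromosome distribution, runs PCA on the centred matrix, and tests
# per-SV carrier-frequency differences between the three groups with
# Fisher's exact test.

suppressPackageStartupMessages(library(svcohort))

base <- file.path("results", "run")
cohort <- read_cohort_table(file.path(base, "cohort.tsv"))
sheet <- read_sample_sheet(file.path(base, "inputs", "sample_sheet.tsv"))

gm <- build_genotype_matrix(cohort, sheet)
write.table(data.frame(sample_id = rownames(gm), as.data.frame(gm),
  check.names = FALSE), file.path(base, "genotype_matrix.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

specific <- find_group_specific(gm, "WXP")
write.table(specific, file.path(base, "group_specific.tsv"), sep = "\t",
  quote = FALSE, row.names = FALSE)
venn <- attr(specific, "venn")
write.table(venn, file.path(base, "venn_counts.tsv"), sep = "\t",
  quote = FALSE, row.names = FALSE)
cat("Venn partition of carrier groups:\n")
for (i in seq_len(nrow(venn))) {
  cat(sprintf("  %-12s %d\n", venn$groups[i], venn$n_svs[i]))
}
spec_tc <- type_counts(cohort[cohort$id %in% specific$sv_id[specific$specific], ])
cat(sprintf("WXP-specific SVs: %d (DEL %d, DUP %d, INS %d, INV %d)\n",
  spec_tc[["total"]], spec_tc[["DEL"]], spec_tc[["DUP"]], spec_tc[["INS"]],
  spec_tc[["INV"]]))

cd <- chrom_distribution(cohort)
write.table(data.frame(chrom = names(cd), n_svs = as.integer(cd)),
  file.path(base, "chrom_counts.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat(sprintf("most SVs on chromosome %s (%d), fewest on %s (%d)\n",
  names(cd)[which.max(cd)], max(cd), names(cd)[which.min(cd)], min(cd)))

pca <- pca_genotypes(gm, 2)
groups <- attr(gm, "groups")[rownames(gm)]
write.table(data.frame(sample_id = rownames(pca$scores), group = groups,
  pca$scores, check.names = FALSE), file.path(base, "pca.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance; group means on PC1: %s\n",
  100 * pca$explained_variance[1], 100 * pca$explained_variance[2],
  paste(sprintf("%s %.2f", names(tapply(pca$scores[, 1], groups, mean)),
    tapply(pca$scores[, 1], groups, mean)), collapse = ", ")))

af <- allele_frequency_test(gm, adjust = TRUE)
write.table(af, file.path(base, "allele_frequency_tests.tsv"), sep = "\t",
  quote = FALSE, row.names = FALSE)
cat(sprintf("SVs with significant carrier-frequency differences (p < 0.05): %d of %d\n",
  sum(af$significant), nrow(af)))
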