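#!/usr/bin/env Rscript
# Stage 3: gene-model annotation.
#
# Classifies each cohort SV's location against the gene model (exon,
# exon-intron boundary, intron, UTR, upstream/downstream within 5 kb,
# intergenic) and assigns a simplified impact class: stop-loss and
# frameshift are high impact; splice-region, UTR, regulatory-flank and
# intronic changes are modifiers.

suppressPackageStartupMessages(library(svcohort))

base <- file.path("results", "run")
cohort <- read_cohort_table(file.path(base, "cohort.tsv"))
genes <- read_gene_models(file.path(base, "inputs", "genes.gff3"))

annotations <- annotate_svs(cohort, genes)
write.table(annotations, file.path(base, "annotations.tsv"), sep = "\t",
  quote = FALSE, row.names = FALSE)
loc <- location_summary(annotations)
write.table(loc, file.path(base, "location_summary.tsv"), sep = "\t",
  quote = FALSE, row.names = FALSE)

cat("location classes:\n")
for (i in seq_len(nrow(loc))) {
  cat(sprintf("  %-20s %5d (%6.2f%%)\n", loc$location[i], loc$count[i],
    loc$percent[i]))
}
cat(sprintf("high-impact SVs: %d; modifiers: %d\n",
  sum(annotations$impact == "high"), sum(annotations$impact == "modifier")))
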