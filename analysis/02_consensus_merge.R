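#!/usr/bin/env Rscript
# Stage 2: dual-caller consensus and cohort merging.
#
# Reads the normalized per-sample caller tables, keeps per-individual SVs
# reported by both callers with >= 3 supporting read pairs, merges calls
# across individuals into a non-redundant cohort set (same type, same
# chromosome, > 25 bp overlap; insertions matched within 25 bp), then keeps
# SVs seen in >= 2 individuals off chromosome Y.

suppressPackageStartupMessages(library(svcohort))

base <- file.path("results", "run")
in_dir <- file.path(base, "inputs")
sheet <- read_sample_sheet(file.path(in_dir, "sample_sheet.tsv"))
callers <- c("callerA", "callerB")

calls <- lapply(callers, function(cid) {
  do.call(rbind, lapply(sheet$sample_id, function(sid) {
    read_caller_calls(file.path(in_dir, "calls", cid, paste0(sid, ".tsv")),
      cid, sid)
  }))
})
cat(sprintf("raw calls: %d (%s) + %d (%s)\n",
  nrow(calls[[1]]), callers[1], nrow(calls[[2]]), callers[2]))

consensus <- do.call(rbind, lapply(sheet$sample_id, function(sid) {
  dual_caller_consensus(
    calls[[1]][calls[[1]]$sample_id == sid, , drop = FALSE],
    calls[[2]][calls[[2]]$sample_id == sid, , drop = FALSE])
}))
cat(sprintf("consensus calls after support and both-caller rules: %d\n",
  nrow(consensus)))

merged <- merge_cohort(consensus)
cohort <- apply_cohort_filters(merged)
tc <- type_counts(cohort)
cat(sprintf("non-redundant cohort SVs: %d (DEL %d, DUP %d, INS %d, INV %d)\n",
  tc[["total"]], tc[["DEL"]], tc[["DUP"]], tc[["INS"]], tc[["INV"]]))

write_cohort_table(cohort, file.path(base, "cohort.tsv"))
export_vcf(cohort, sheet$sample_id, file.path(base, "cohort.vcf"))
cat("cohort table and VCF written under", base, "\n")
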