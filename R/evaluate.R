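#' Recovery statistics of a simulated run against its ground truth
#'
#' Measures how faithfully the consensus-and-merge pipeline reconstructs the
#' planted cohort. A planted SV is *eligible* for merge recovery when it lies
#' on a retained chromosome and at least two samples carry a call for it from
#' both callers at or above the support threshold (the pipeline cannot be
#' expected to recover SVs its inputs never showed twice). A planted SV
#' *matches* a cohort record when the two satisfy the merge rule
#' ([sv_mergeable()]); eligible SVs should match exactly one record.
#'
#' Group-specific recovery is unconditional: every planted SV whose realised
#' carriers are confined to `target_group` counts, recovered when it matches
#' exactly one cohort record flagged specific by [find_group_specific()].
#' False specifics are flagged records matching no such planted SV.
#'
#' @param truth truth table from [simulate_cohort()].
#' @param calls_a,calls_b simulated caller outputs (with their `truth_id`
#'   column).
#' @param cohort filtered cohort table.
#' @param specific optional result of [find_group_specific()] on the cohort.
#' @param target_group group label for the specificity evaluation.
#' @param min_support,min_overlap,ins_window,drop_chroms pipeline thresholds
#'   (defaults as in the pipeline).
#' @return list with `n_eligible`, `merged_once_rate`, `n_specific_truth`,
#'   `specific_recovery_rate`, `n_false_specific`.
#' @export
recovery_stats <- function(truth, calls_a, calls_b, cohort, specific = NULL,
                           target_group = "WXP", min_support = 3,
                           min_overlap = 25, ins_window = 25,
                           drop_chroms = "Y") {
  seen <- function(calls) {
    ok <- !is.na(calls$truth_id) & calls$support >= min_support
    unique(paste(calls$sample_id[ok], calls$truth_id[ok]))
  }
  both <- intersect(seen(calls_a), seen(calls_b))
  per_sv <- table(sub("^\\S+ ", "", both))
  eligible_ids <- names(per_sv)[per_sv >= 2]
  eligible_ids <- eligible_ids[
    !(truth$chrom[match(eligible_ids, truth$sv_id)] %in% drop_chroms)]

  match_count <- function(tr) {
    same <- cohort$svtype == tr$svtype & cohort$chrom == tr$chrom
    if (!any(same)) return(0L)
    sub <- cohort[same, , drop = FALSE]
    if (tr$svtype == "INS") {
      sum(abs(sub$start - tr$start) <= ins_window)
    } else {
      sum(pmin(sub$end, tr$end) - pmax(sub$start, tr$start) > min_overlap)
    }
  }
  n_match <- vapply(eligible_ids, function(tid) {
    match_count(truth[truth$sv_id == tid, ])
  }, integer(1))
  out <- list(
    n_eligible = length(eligible_ids),
    merged_once_rate = if (length(eligible_ids)) mean(n_match == 1) else NA_real_)

  spec_truth <- truth[!is.na(truth$specific_to) &
    truth$specific_to == target_group &
    !(truth$chrom %in% drop_chroms), , drop = FALSE]
  out$n_specific_truth <- nrow(spec_truth)
  if (!is.null(specific)) {
    called_ids <- specific$sv_id[specific$specific]
    hit_one <- vapply(seq_len(nrow(spec_truth)), function(i) {
      tr <- spec_truth[i, ]
      same <- cohort$id %in% called_ids & cohort$svtype == tr$svtype &
        cohort$chrom == tr$chrom
      sub <- cohort[same, , drop = FALSE]
      n <- if (tr$svtype == "INS") {
        sum(abs(sub$start - tr$start) <= ins_window)
      } else {
        sum(pmin(sub$end, tr$end) - pmax(sub$start, tr$start) > min_overlap)
      }
      n == 1L
    }, logical(1))
    out$specific_recovery_rate <- if (nrow(spec_truth)) mean(hit_one) else NA_real_
    # called-specific records not explained by any planted target-specific SV
    false_spec <- vapply(called_ids, function(id) {
      cr <- cohort[cohort$id == id, ]
      same <- spec_truth$svtype == cr$svtype & spec_truth$chrom == cr$chrom
      sub <- spec_truth[same, , drop = FALSE]
      n <- if (cr$svtype == "INS") {
        sum(abs(sub$start - cr$start) <= ins_window)
      } else {
        sum(pmin(sub$end, cr$end) - pmax(sub$start, cr$start) > min_overlap)
      }
      n == 0L
    }, logical(1))
    out$n_false_specific <- sum(false_spec)
  }
  out
}
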