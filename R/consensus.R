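#' Can two SV records be merged?
#'
#' Two records are mergeable when they have the same `svtype`, lie on the same
#' chromosome, and — for the span types DEL/DUP/INV — overlap by strictly more
#' than `min_overlap` bp (`min(end_a, end_b) - max(start_a, start_b) >
#' min_overlap`). Insertions have zero-width intervals, so they are matched by
#' breakpoint distance instead: `|start_a - start_b| <= ins_window`.
#'
#' @param a,b one-row (or equal-length) SV data.frames with `chrom`, `start`,
#'   `end`, `svtype`.
#' @param min_overlap required overlap in bp, strict (default 25).
#' @param ins_window breakpoint window for insertions in bp (default 25).
#' @return logical vector.
#' @export
sv_mergeable <- function(a, b, min_overlap = 25, ins_window = 25) {
  same <- a$svtype == b$svtype & a$chrom == b$chrom
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  span_ok <- ov > min_overlap
  ins_ok <- abs(a$start - b$start) <= ins_window
  same & ifelse(a$svtype == "INS", ins_ok, span_ok)
}

# All mergeable index pairs (i < j) within one table, grouped by
# (chrom, svtype) and found with IRanges; INS points are matched by padding
# start positions with ins_window so interval overlap == breakpoint distance.
mergeable_pairs <- function(calls, min_overlap = 25, ins_window = 25) {
  if (nrow(calls) < 2) {
    return(data.frame(i = integer(0), j = integer(0), score = numeric(0)))
  }
  key <- paste(calls$chrom, calls$svtype, sep = "\r")
  out <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    if (length(idx) < 2) return(NULL)
    ins <- calls$svtype[idx[1]] == "INS"
    if (ins) {
      ir <- IRanges::IRanges(start = calls$start[idx],
        end = calls$start[idx] + ins_window)
      hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    } else {
      ir <- IRanges::IRanges(start = calls$start[idx], end = calls$end[idx])
      hits <- IRanges::findOverlaps(ir, minoverlap = min_overlap + 1,
        drop.self = TRUE, drop.redundant = TRUE)
    }
    if (length(hits) == 0) return(NULL)
    i <- idx[S4Vectors::queryHits(hits)]
    j <- idx[S4Vectors::subjectHits(hits)]
    # score: overlap bp for span types (higher is better), negative breakpoint
    # distance for INS, on a shared "bigger is better" scale
    score <- if (ins) {
      -abs(calls$start[i] - calls$start[j])
    } else {
      pmin(calls$end[i], calls$end[j]) - pmax(calls$start[i], calls$start[j])
    }
    # findOverlaps with the inclusive-end IRanges encoding counts one extra
    # base for span types; re-check the strict bp threshold on raw coordinates
    keep <- if (ins) rep(TRUE, length(i)) else score > min_overlap
    data.frame(i = pmin(i, j)[keep], j = pmax(i, j)[keep], score = score[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(i = integer(0), j = integer(0), score = numeric(0)) else out
}

#' Per-individual dual-caller consensus
#'
#' Retains only SVs independently reported by both callers for one
#' individual. Each caller's records must first pass the read-pair support
#' filter (`support >= min_support`, default 3); surviving records are then
#' matched one-to-one across callers under the [sv_mergeable()] rule, greedily
#' by best overlap (smallest breakpoint distance for INS), ties broken by
#' leftmost start then smallest length. The consensus record takes the
#' coordinates of the matched member with the higher support (ties favour the
#' first caller) and the pair's maximum support.
#'
#' @param calls_a,calls_b call data.frames from the two callers, one sample.
#' @param min_support minimum supporting read pairs per caller record.
#' @param min_overlap,ins_window matching thresholds, see [sv_mergeable()].
#' @return data.frame of consensus SVs with columns `sample_id`, `chrom`,
#'   `start`, `end`, `svtype`, `length`, `support`, and the contributing
#'   record coordinates `caller_a`/`caller_b` identity columns
#'   `a_start`, `a_end`, `b_start`, `b_end`.
#' @export
dual_caller_consensus <- function(calls_a, calls_b, min_support = 3,
                                  min_overlap = 25, ins_window = 25) {
  samples <- unique(c(calls_a$sample_id, calls_b$sample_id))
  if (length(samples) > 1) {
    stop("dual_caller_consensus expects calls from a single sample, got: ",
      paste(samples, collapse = ", "))
  }
  a <- calls_a[calls_a$support >= min_support, , drop = FALSE]
  b <- calls_b[calls_b$support >= min_support, , drop = FALSE]
  empty <- data.frame(sample_id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), svtype = character(0),
    length = integer(0), support = integer(0),
    caller_a = character(0), caller_b = character(0),
    a_start = integer(0), a_end = integer(0),
    b_start = integer(0), b_end = integer(0), stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)

  # candidate cross-caller pairs via the pooled-pair machinery
  pool <- rbind(
    a[, c("chrom", "start", "end", "svtype", "length", "support")],
    b[, c("chrom", "start", "end", "svtype", "length", "support")])
  side <- rep(c("a", "b"), c(nrow(a), nrow(b)))
  pairs <- mergeable_pairs(pool, min_overlap, ins_window)
  if (nrow(pairs) > 0) {
    cross <- side[pairs$i] != side[pairs$j]
    pairs <- pairs[cross, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(empty)
  ai <- ifelse(side[pairs$i] == "a", pairs$i, pairs$j)
  bi <- ifelse(side[pairs$i] == "a", pairs$j, pairs$i) - nrow(a)

  # greedy one-to-one matching: best overlap first, then leftmost, smallest
  ord <- order(-pairs$score,
    pmin(a$start[ai], b$start[bi]),
    pmin(sv_length(a)[ai], sv_length(b)[bi]))
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(length(ord))
  for (k in ord) {
    if (!used_a[ai[k]] && !used_b[bi[k]]) {
      used_a[ai[k]] <- TRUE; used_b[bi[k]] <- TRUE; keep[k] <- TRUE
    }
  }
  ai <- ai[keep]; bi <- bi[keep]
  rep_a <- a$support[ai] >= b$support[bi]  # ties -> caller A's record
  pick <- function(col) ifelse(rep_a, a[[col]][ai], b[[col]][bi])
  res <- data.frame(
    sample_id = samples,
    chrom = as.character(pick("chrom")),
    start = pick("start"), end = pick("end"),
    svtype = as.character(pick("svtype")), length = pick("length"),
    support = pmax(a$support[ai], b$support[bi]),
    caller_a = a$caller_id[ai], caller_b = b$caller_id[bi],
    a_start = a$start[ai], a_end = a$end[ai],
    b_start = b$start[bi], b_end = b$end[bi],
    stringsAsFactors = FALSE)
  res <- res[order(match(res$chrom, unique(res$chrom)[chrom_order(unique(res$chrom))]),
    res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge consensus SVs across individuals into a non-redundant call set
#'
#' Single-linkage transitive clustering under the [sv_mergeable()] relation:
#' any chain of pairwise-mergeable same-type calls collapses into one
#' cohort-level SV. Each cluster is represented by the member with the highest
#' support (ties: leftmost start, then smallest length) — an observed
#' interval, never a coordinate average — and carries the set of distinct
#' sample IDs of its members. The result is sorted by (chrom, start) and given
#' IDs `sv_%05d`; it is invariant to the input row order.
#'
#' @param consensus consensus call data.frame across all samples (columns
#'   `sample_id`, `chrom`, `start`, `end`, `svtype`, `length`, `support`).
#' @param min_overlap,ins_window clustering thresholds, see [sv_mergeable()].
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `svtype`,
#'   `length`, `support`, `n_carriers`, `carriers` (comma-joined, sorted);
#'   the member-to-cluster assignment is attached as attribute `"members"`
#'   (the input rows, canonically ordered, plus a `cluster` column).
#' @export
merge_cohort <- function(consensus, min_overlap = 25, ins_window = 25) {
  empty <- data.frame(id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), svtype = character(0),
    length = integer(0), support = integer(0), n_carriers = integer(0),
    carriers = character(0), stringsAsFactors = FALSE)
  if (is.null(consensus) || nrow(consensus) == 0) {
    attr(empty, "members") <- consensus
    return(empty)
  }
  # canonical internal order makes the result independent of input order
  x <- consensus[order(consensus$chrom, consensus$svtype, consensus$start,
    consensus$end, consensus$sample_id, -consensus$support), , drop = FALSE]
  rownames(x) <- NULL
  n <- nrow(x)
  parent <- seq_len(n)
  find_root <- function(i) {  # union-find with path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pairs <- mergeable_pairs(x, min_overlap, ins_window)
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find_root(pairs$i[k])
      rj <- find_root(pairs$j[k])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find_root, integer(1))
  cl <- match(root, unique(root))
  x$cluster <- cl
  clf <- factor(cl, levels = seq_len(max(cl)))  # keep numeric level order

  reps <- vapply(split(seq_len(n), clf), function(idx) {
    idx[order(-x$support[idx], x$start[idx], sv_length(x)[idx])][1]
  }, integer(1))
  carriers <- vapply(split(x$sample_id, clf), function(s) {
    paste(sort(unique(s)), collapse = ",")
  }, character(1))
  n_carriers <- vapply(split(x$sample_id, clf),
    function(s) length(unique(s)), integer(1))
  merged <- data.frame(
    chrom = x$chrom[reps], start = x$start[reps], end = x$end[reps],
    svtype = x$svtype[reps], length = x$length[reps],
    support = x$support[reps],
    n_carriers = n_carriers, carriers = carriers,
    stringsAsFactors = FALSE)
  ord <- order(match(merged$chrom,
    unique(merged$chrom)[chrom_order(unique(merged$chrom))]),
    merged$start, merged$end, merged$svtype)
  merged <- merged[ord, , drop = FALSE]
  merged <- cbind(id = sprintf("sv_%05d", seq_len(nrow(merged))), merged,
    stringsAsFactors = FALSE)
  rownames(merged) <- NULL
  # remap member cluster numbers to the sorted output order
  x$cluster <- match(x$cluster, ord)
  attr(merged, "members") <- x
  merged
}

#' Cohort-level retention filters
#'
#' Keeps merged SVs detected in at least `min_individuals` individuals
#' (default 2) and drops whole chromosomes (default Y, removing the influence
#' of sex on detection). Counts removed per rule are reported via `message()`
#' and attached as attribute `"filter_log"`.
#'
#' @param svs merged-SV data.frame from [merge_cohort()].
#' @param min_individuals minimum carrier count.
#' @param drop_chroms chromosomes to remove entirely.
#' @return filtered data.frame, IDs reassigned in (chrom, start) order.
#' @export
apply_cohort_filters <- function(svs, min_individuals = 2, drop_chroms = "Y") {
  on_dropped <- svs$chrom %in% drop_chroms
  few <- svs$n_carriers < min_individuals
  log <- c(records_in = nrow(svs),
    removed_chrom = sum(on_dropped),
    removed_min_individuals = sum(few & !on_dropped),
    records_kept = sum(!few & !on_dropped))
  message(sprintf(
    "cohort filters: %d in, %d removed on %s, %d removed below %d carriers, %d kept",
    log[["records_in"]], log[["removed_chrom"]],
    paste(drop_chroms, collapse = "/"), log[["removed_min_individuals"]],
    min_individuals, log[["records_kept"]]))
  out <- svs[!few & !on_dropped, , drop = FALSE]
  if (nrow(out) > 0 && "id" %in% names(out)) {
    out$id <- sprintf("sv_%05d", seq_len(nrow(out)))
  }
  rownames(out) <- NULL
  attr(out, "filter_log") <- log
  out
}

#' Count SVs per type
#'
#' @param svs any SV table with an `svtype` column (or a character vector of
#'   types).
#' @return named integer vector with entries `DEL`, `DUP`, `INS`, `INV` and
#'   `total` (the sum of the four).
#' @export
type_counts <- function(svs) {
  types <- if (is.data.frame(svs)) svs$svtype else svs
  counts <- vapply(SV_TYPES, function(t) sum(types == t), integer(1))
  c(counts, total = sum(counts))
}
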