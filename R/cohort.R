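#' Build the presence/absence genotype matrix
#'
#' Samples in rows, SVs in columns; entry 1 when the sample is a carrier of
#' the SV. Group labels from the sample sheet are attached as attribute
#' `"groups"` (named by sample).
#'
#' @param svs cohort table (columns `id`, `carriers`).
#' @param sample_sheet data.frame with `sample_id`, `group`.
#' @return integer matrix with `dimnames = list(sample_ids, sv_ids)`.
#' @export
build_genotype_matrix <- function(svs, sample_sheet) {
  samples <- sample_sheet$sample_id
  m <- matrix(0L, nrow = length(samples), ncol = nrow(svs),
    dimnames = list(samples, svs$id))
  if (nrow(svs) > 0) {
    carriers <- strsplit(svs$carriers, ",", fixed = TRUE)
    unknown <- setdiff(unlist(carriers), samples)
    if (length(unknown) > 0) {
      stop("carrier(s) not in the sample sheet: ", paste(unknown, collapse = ", "))
    }
    for (j in seq_along(carriers)) m[carriers[[j]], j] <- 1L
  }
  attr(m, "groups") <- setNames(sample_sheet$group, sample_sheet$sample_id)
  m
}

# per-group carrier counts for every SV column
.group_carrier_counts <- function(matrix) {
  groups <- attr(matrix, "groups")[rownames(matrix)]
  glabels <- unique(groups)
  counts <- vapply(glabels, function(g) {
    colSums(matrix[groups == g, , drop = FALSE])
  }, numeric(ncol(matrix)))
  if (ncol(matrix) == 1) counts <- matrix(counts, nrow = 1,
    dimnames = list(colnames(matrix), glabels))
  counts  # svs x groups
}

#' Find group-specific SVs
#'
#' An SV is specific to `target_group` when it has at least one carrier in
#' that group and none in any other group. The full per-SV group carrier
#' counts and the three-set (or k-set) Venn partition are returned alongside.
#'
#' @param matrix genotype matrix from [build_genotype_matrix()].
#' @param target_group group label to screen for.
#' @return data.frame with `sv_id`, one carrier-count column per group,
#'   `specific_to` (the single carrying group, or NA), and `specific`
#'   (logical, specific to `target_group`); the Venn partition counts (one
#'   row per group combination) are attached as attribute `"venn"`.
#' @export
find_group_specific <- function(matrix, target_group) {
  groups <- attr(matrix, "groups")
  if (!(target_group %in% groups)) stop("unknown group: ", target_group)
  counts <- .group_carrier_counts(matrix)
  glabels <- colnames(counts)
  pos <- counts > 0
  n_groups_hit <- rowSums(pos)
  specific_to <- ifelse(n_groups_hit == 1,
    glabels[apply(pos, 1, which.max)], NA_character_)
  res <- data.frame(sv_id = colnames(matrix), stringsAsFactors = FALSE)
  for (g in glabels) res[[paste0("carriers_", g)]] <- as.integer(counts[, g])
  res$specific_to <- specific_to
  res$specific <- !is.na(specific_to) & specific_to == target_group
  combo <- apply(pos, 1, function(p) paste(sort(glabels[p]), collapse = "&"))
  combo[n_groups_hit == 0] <- "(none)"
  venn <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(venn) <- c("groups", "n_svs")
  attr(res, "venn") <- venn
  res
}

#' Per-chromosome SV counts
#'
#' @param svs cohort table with a `chrom` column.
#' @return named integer vector in natural chromosome order (autosomes
#'   numerically, then X, then Y).
#' @export
chrom_distribution <- function(svs) {
  if (nrow(svs) == 0) return(setNames(integer(0), character(0)))
  tab <- table(svs$chrom)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[chrom_order(names(counts))]
}

#' PCA of the presence/absence genotype matrix
#'
#' Columns are mean-centred (no scaling) and decomposed by SVD. The sign of
#' each component is fixed by forcing its largest-magnitude loading positive,
#' so results are deterministic and invariant to column permutation up to
#' that convention. A matrix with zero total variance yields all-zero
#' coordinates with a warning.
#'
#' @param matrix genotype matrix from [build_genotype_matrix()].
#' @param n_components number of components (< number of samples).
#' @return list with `scores` (samples x components), `explained_variance`
#'   (fractions, non-increasing), `loadings`.
#' @export
pca_genotypes <- function(matrix, n_components = 2) {
  n <- nrow(matrix)
  if (n < 2) stop("need at least 2 samples")
  if (n_components >= n) stop("n_components must be < number of samples")
  x <- sweep(matrix, 2, colMeans(matrix))
  if (all(abs(x) < 1e-12)) {
    warning("genotype matrix has zero variance; returning zero coordinates")
    scores <- matrix(0, n, n_components,
      dimnames = list(rownames(matrix), paste0("PC", seq_len(n_components))))
    return(list(scores = scores,
      explained_variance = rep(0, n_components), loadings = NULL))
  }
  sv <- svd(x, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  # sign convention: largest |loading| of each component positive; ties are
  # broken by column name so the convention is column-permutation invariant
  cn <- if (is.null(colnames(x))) as.character(seq_len(ncol(x))) else colnames(x)
  for (k in seq_len(n_components)) {
    cand <- which(abs(sv$v[, k]) >= max(abs(sv$v[, k])) - 1e-8)
    pivot <- cand[order(cn[cand])][1]
    if (sv$v[pivot, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  scores <- sv$u %*% diag(d, nrow = n_components)
  dimnames(scores) <- list(rownames(matrix), paste0("PC", seq_len(n_components)))
  ev <- sv$d^2 / sum(svd(x)$d^2)
  list(scores = scores,
    explained_variance = ev[seq_len(n_components)],
    loadings = sv$v)
}

#' Exact test of carrier-frequency differences between groups
#'
#' For each SV, the groups x (carrier, non-carrier) contingency table is
#' tested with Fisher's exact test (for more than two groups, the exact
#' conditional test over all tables with the observed margins; the p-value is
#' the total probability of tables no more probable than the observed one).
#' "Allele frequency" here is carrier frequency, the pipeline's genotype
#' model being presence/absence.
#'
#' @param matrix genotype matrix from [build_genotype_matrix()].
#' @param sv_ids SVs to test (default: all columns).
#' @param adjust if `TRUE`, add Benjamini-Hochberg adjusted p-values.
#' @param alpha significance threshold used for the `significant` flag
#'   (unadjusted by default, matching common reporting practice).
#' @return data.frame with `sv_id`, per-group carrier frequencies
#'   (`freq_<group>`), `p`, `significant`, and `padj` when requested.
#' @export
allele_frequency_test <- function(matrix, sv_ids = colnames(matrix),
                                  adjust = FALSE, alpha = 0.05) {
  groups <- attr(matrix, "groups")[rownames(matrix)]
  glabels <- unique(groups)
  if (length(glabels) < 2) stop("need at least two groups")
  gsize <- vapply(glabels, function(g) sum(groups == g), integer(1))
  if (any(gsize == 0)) stop("group with zero samples")
  res <- lapply(sv_ids, function(id) {
    carrier <- matrix[, id]
    k <- vapply(glabels, function(g) sum(carrier[groups == g]), numeric(1))
    tab <- rbind(carrier = k, non_carrier = gsize - k)
    p <- stats::fisher.test(tab, workspace = 2e6)$p.value
    out <- data.frame(sv_id = id, stringsAsFactors = FALSE)
    for (g in glabels) out[[paste0("freq_", g)]] <- k[[g]] / gsize[[g]]
    out$p <- min(p, 1)
    out
  })
  res <- do.call(rbind, res)
  if (adjust) res$padj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  rownames(res) <- NULL
  res
}
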