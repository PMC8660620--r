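#' Hypergeometric over-representation test of gene sets
#'
#' For each term, the p-value is the upper-tail hypergeometric probability
#' P(X >= k) of drawing at least the observed overlap `k` when `n` query
#' genes are sampled without replacement from a background of `N` genes of
#' which `K` belong to the term. One-tailed (enrichment only); no
#' multiple-testing correction is applied by default. Terms with no overlap
#' report p = 1.
#'
#' @param query_genes character vector of query gene ids (must lie in the
#'   background).
#' @param gene_sets list of gene sets (`term_id`, `term_name`, `genes`), as
#'   read by [read_gmt()]. Each set is intersected with the background before
#'   testing.
#' @param background character vector: the gene universe.
#' @return data.frame sorted by p with columns `term_id`, `term_name`, `k`,
#'   `n`, `K`, `N`, `p`, `overlap_genes` (comma-joined).
#' @export
hypergeometric_enrichment <- function(query_genes, gene_sets, background) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  query <- unique(query_genes)
  if (!all(query %in% background)) {
    stop("query genes outside the background: ",
      paste(setdiff(query, background), collapse = ", "))
  }
  N <- length(background)
  n <- length(query)
  res <- lapply(gene_sets, function(gs) {
    term <- intersect(unique(gs$genes), background)
    K <- length(term)
    hit <- intersect(query, term)
    k <- length(hit)
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = gs$term_id, term_name = gs$term_name,
      k = k, n = n, K = K, N = N, p = min(p, 1),
      overlap_genes = paste(sort(hit), collapse = ","),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Three-criterion candidate screen for phenotype-associated SVs
#'
#' Starting from group-specific SVs (criterion 1, satisfied by
#' construction), an (SV, gene) pair becomes a candidate when the gene
#' either (criterion 2) belongs to at least one enriched term
#' (`p < alpha`) whose name matches `tag_pattern` — a data-driven way of
#' marking terms as relevant to the phenotype — or (criterion 3)
#' appears in the curated aging-gene list. Intergenic SVs carry no gene and
#' are never candidates.
#'
#' @param specific_svs cohort table restricted to group-specific SVs.
#' @param annotations matching annotation rows from [annotate_svs()].
#' @param enrichment result of [hypergeometric_enrichment()] on the genes hit
#'   by the specific SVs.
#' @param aging_genes character vector of aging-associated gene ids.
#' @param alpha enrichment significance threshold (default 0.05, raw p).
#' @param tag_pattern regular expression selecting relevant term names
#'   (default `"skin|aging"`); tags live in the gene-set file, not in code.
#' @return data.frame with one row per candidate (SV, gene) pair: `id`,
#'   `chrom`, `start`, `end`, `length`, `svtype`, `location`,
#'   `location_string`, `gene`, `evidence` (`enriched_term`, `aging_list` or
#'   both, comma-joined).
#' @export
screen_candidates <- function(specific_svs, annotations, enrichment,
                              aging_genes = character(0), alpha = 0.05,
                              tag_pattern = "skin|aging") {
  stopifnot(nrow(specific_svs) == nrow(annotations))
  relevant <- enrichment[enrichment$p < alpha &
    grepl(tag_pattern, enrichment$term_name, ignore.case = TRUE), , drop = FALSE]
  enriched_genes <- unique(unlist(strsplit(relevant$overlap_genes, ",", fixed = TRUE)))
  enriched_genes <- enriched_genes[nzchar(enriched_genes)]
  rows <- list()
  for (i in seq_len(nrow(specific_svs))) {
    gids <- annotations$genes[i]
    if (!nzchar(gids)) next
    for (gid in strsplit(gids, ",", fixed = TRUE)[[1]]) {
      evidence <- c(
        if (gid %in% enriched_genes) "enriched_term",
        if (gid %in% aging_genes) "aging_list")
      if (length(evidence) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        id = specific_svs$id[i], chrom = specific_svs$chrom[i],
        start = specific_svs$start[i], end = specific_svs$end[i],
        length = specific_svs$length[i], svtype = specific_svs$svtype[i],
        location = annotations$location[i],
        location_string = annotations$location_string[i],
        gene = gid, evidence = paste(evidence, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(id = character(0), chrom = character(0),
      start = integer(0), end = integer(0), length = integer(0),
      svtype = character(0), location = character(0),
      location_string = character(0), gene = character(0),
      evidence = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
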