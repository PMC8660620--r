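# Shared fixture builders and independent oracles.

# quick SV call table constructor
make_calls <- function(chrom, start, end, svtype, support = 5,
                       caller_id = "A", sample_id = "s1",
                       length = NULL) {
  if (is.null(length)) length <- ifelse(svtype == "INS", 60L, end - start)
  data.frame(caller_id = caller_id, sample_id = sample_id,
    chrom = as.character(chrom), start = start, end = end,
    svtype = svtype, length = length, support = support,
    stringsAsFactors = FALSE)
}

# toy two-exon plus-strand gene used across annotation tests:
# exon1 100-200, intron1 201-300, exon2 301-400
toy_gene <- function(strand = 1L, utr5 = 0, utr3 = 0) {
  gene_model("toy", chrom = "1", strand = strand,
    exons = data.frame(start = c(100L, 301L), end = c(200L, 400L)),
    utr5_len = utr5, utr3_len = utr3)
}

# a gene with n_ex equal-sized exons, for reproducing published location strings
uniform_gene <- function(n_ex, strand, exon_len = 200L, intron_len = 1000L,
                         origin = 10000L, gene_id = "g") {
  starts <- origin + (0:(n_ex - 1)) * (exon_len + intron_len)
  gene_model(gene_id, chrom = "1", strand = strand,
    exons = data.frame(start = starts, end = starts + exon_len - 1L),
    utr5_len = 50, utr3_len = 50 + (n_ex * exon_len - 100) %% 3)
}

# --- independent clustering oracle: union-find over ALL pairwise
# sv_mergeable() relations, O(n^2), no interval index involved
oracle_clusters <- function(calls, min_overlap = 25, ins_window = 25) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sv_mergeable(calls[i, ], calls[j, ], min_overlap, ins_window)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# partition of a 'uid' column into clusters, as a canonical set of sets
partition_of <- function(uids, cluster) {
  unname(sort(vapply(split(uids, cluster), function(u)
    paste(sort(u), collapse = "|"), character(1))))
}

# random clustering instance: coordinates packed tightly to force overlaps
random_instance <- function(n, seed) {
  set.seed(seed)
  types <- sample(c("DEL", "DUP", "INS", "INV"), n, replace = TRUE,
    prob = c(0.6, 0.15, 0.15, 0.1))
  chrom <- sample(c("1", "2"), n, replace = TRUE)
  start <- sample.int(3000, n, replace = TRUE)
  len <- sample(30:400, n, replace = TRUE)
  end <- ifelse(types == "INS", start, start + len)
  make_calls(chrom, start, end, types,
    support = sample(3:20, n, replace = TRUE),
    sample_id = paste0("s", sample(1:6, n, replace = TRUE)))
}

# --- exact Fisher oracle: full enumeration of 2 x g tables with the
# observed margins; p = total probability of tables no more probable than
# the observed one (with fisher.test's relative tie tolerance)
fisher_oracle <- function(k, sizes) {
  K <- sum(k); N <- sum(sizes); g <- length(sizes)
  prob_table <- function(kk) prod(choose(sizes, kk)) / choose(N, K)
  p_obs <- prob_table(k)
  enum <- function(idx, remaining, acc) {
    if (idx == g) {
      if (remaining <= sizes[g]) {
        pr <- prob_table(c(acc, remaining))
        if (pr <= p_obs * (1 + 1e-7)) return(pr)
      }
      return(0)
    }
    tot <- 0
    for (kk in 0:min(sizes[idx], remaining)) {
      tot <- tot + enum(idx + 1, remaining - kk, c(acc, kk))
    }
    tot
  }
  enum(1, K, numeric(0))
}

# genotype matrix from explicit carrier counts per group (one SV)
gm_from_counts <- function(k, sizes, groups = paste0("G", seq_along(sizes))) {
  sheet <- data.frame(
    sample_id = unlist(lapply(seq_along(sizes), function(i)
      paste0(groups[i], "_", seq_len(sizes[i])))),
    group = rep(groups, sizes), stringsAsFactors = FALSE)
  carriers <- unlist(lapply(seq_along(sizes), function(i)
    paste0(groups[i], "_", seq_len(sizes[i]))[seq_len(k[i])]))
  svs <- data.frame(id = "sv_00001", carriers = paste(carriers, collapse = ","),
    stringsAsFactors = FALSE)
  build_genotype_matrix(svs, sheet)
}

# --- exact hypergeometric upper-tail oracle by term-by-term summation
hyper_oracle <- function(k, K, N, n) {
  if (k == 0) return(1)
  sum(vapply(k:min(K, n), function(j) dhyper(j, K, N - K, n), numeric(1)))
}

# simulated caller pair + consensus + cohort for one config (shared by
# recovery tests); returns all intermediates
run_sim_pipeline <- function(cfg) {
  genes <- simulate_gene_models(cfg)
  truth <- simulate_cohort(cfg, genes)
  ca <- simulate_caller_output(truth, cfg, "callerA")
  cb <- simulate_caller_output(truth, cfg, "callerB")
  sheet <- sim_sample_sheet(cfg)
  cons <- do.call(rbind, lapply(sheet$sample_id, function(sid) {
    dual_caller_consensus(ca[ca$sample_id == sid, , drop = FALSE],
      cb[cb$sample_id == sid, , drop = FALSE])
  }))
  merged <- merge_cohort(cons)
  cohort <- suppressMessages(apply_cohort_filters(merged))
  list(genes = genes, truth = truth, ca = ca, cb = cb, sheet = sheet,
    consensus = cons, merged = merged, cohort = cohort)
}
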