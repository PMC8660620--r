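#' Configuration for the synthetic cohort simulator
#'
#' Defaults emulate a 35-animal resequencing cohort split into a case group
#' (WXP, n = 7), a breed-matched control group (XP, n = 7) and an outgroup
#' (EUP, n = 21), genotyped for cohort-shared and group-specific SVs by two
#' noisy callers. Planted SV lengths are log-uniform between 50 and 2,000 bp
#' and the type mix approximates a deletion-dominated cohort call set
#' (DEL 0.86, DUP 0.07, INS 0.06, INV 0.01).
#'
#' @param seed integer seed driving every stage of the simulation.
#' @param n_autosomes,autosome_length,sex_chrom_length,include_sex_chroms
#'   genome layout; sex chromosomes X and Y are appended when requested (Y
#'   carries no genes and exists to exercise the chromosome filter).
#' @param n_genes,exons_per_gene gene-model scale.
#' @param group_sizes named integer vector of samples per group.
#' @param n_shared_svs number of planted SVs with carriers drawn across all
#'   groups.
#' @param n_specific_svs named integer vector: planted SVs whose carriers are
#'   confined to one group (at least 2 carriers each, so the cohort
#'   two-individual filter cannot remove a correctly recovered one).
#' @param sv_length_range log-uniform length range in bp.
#' @param type_mix named probabilities over DEL/DUP/INS/INV.
#' @param location_mix named probabilities over the location classes used to
#'   stratify planted SV positions (every class stays non-empty in
#'   expectation).
#' @param carrier_freq_range per-SV carrier frequency, drawn uniformly.
#' @param jitter_sd caller breakpoint jitter (bp, sd of rounded Gaussian).
#' @param fn_rate per-caller per-carrier false-negative rate.
#' @param fp_per_mb per-caller false-positive calls per Mb per sample.
#' @param support_mean,support_min supporting read-pair distribution
#'   (`support_min` plus a Poisson with mean `support_mean - support_min`).
#' @param flank upstream/downstream flank used for placement and annotation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_autosomes = 5, autosome_length = 8e6,
                       sex_chrom_length = 4e6, include_sex_chroms = TRUE,
                       n_genes = 120, exons_per_gene = 5,
                       group_sizes = c(WXP = 7, XP = 7, EUP = 21),
                       n_shared_svs = 300,
                       n_specific_svs = c(WXP = 40, XP = 25, EUP = 25),
                       sv_length_range = c(50, 2000),
                       type_mix = c(DEL = 0.86, DUP = 0.07, INS = 0.06, INV = 0.01),
                       location_mix = c(intron = 0.45, intergenic = 0.38,
                         upstream_downstream = 0.11, exon = 0.03,
                         exon_intron = 0.02, utr = 0.01),
                       carrier_freq_range = c(0.15, 0.9),
                       jitter_sd = 10, fn_rate = 0.05, fp_per_mb = 2,
                       support_mean = 10, support_min = 1,
                       flank = 5000) {
  stopifnot(fn_rate >= 0, fn_rate <= 1, jitter_sd >= 0, fp_per_mb >= 0)
  if (any(n_specific_svs > 0 & group_sizes[names(n_specific_svs)] < 2)) {
    stop("groups with planted specific SVs need at least 2 samples")
  }
  structure(list(seed = seed, n_autosomes = n_autosomes,
    autosome_length = autosome_length, sex_chrom_length = sex_chrom_length,
    include_sex_chroms = include_sex_chroms, n_genes = n_genes,
    exons_per_gene = exons_per_gene, group_sizes = group_sizes,
    n_shared_svs = n_shared_svs, n_specific_svs = n_specific_svs,
    sv_length_range = sv_length_range, type_mix = type_mix,
    location_mix = location_mix, carrier_freq_range = carrier_freq_range,
    jitter_sd = jitter_sd, fn_rate = fn_rate, fp_per_mb = fp_per_mb,
    support_mean = support_mean, support_min = support_min, flank = flank),
    class = "sim_config")
}

#' Simulated chromosomes
#'
#' @param config a [sim_config()].
#' @return data.frame with `chrom` and `length` (bp).
#' @export
sim_chromosomes <- function(config) {
  chrom <- as.character(seq_len(config$n_autosomes))
  len <- rep(config$autosome_length, config$n_autosomes)
  if (config$include_sex_chroms) {
    chrom <- c(chrom, "X", "Y")
    len <- c(len, config$sex_chrom_length, config$sex_chrom_length)
  }
  data.frame(chrom = chrom, length = len, stringsAsFactors = FALSE)
}

#' Simulated sample sheet
#'
#' Sample ids are `<group><i>` (WXP1, WXP2, ...).
#'
#' @param config a [sim_config()].
#' @return data.frame with `sample_id`, `group`.
#' @export
sim_sample_sheet <- function(config) {
  g <- config$group_sizes
  data.frame(
    sample_id = unlist(lapply(names(g), function(nm) paste0(nm, seq_len(g[[nm]])))),
    group = rep(names(g), g),
    stringsAsFactors = FALSE)
}

#' Simulate non-overlapping gene models
#'
#' Genes are laid out sequentially on every non-Y chromosome, separated by
#' more than twice the annotation flank so that upstream/downstream regions of
#' neighbouring genes never overlap. Each gene carries one transcript with
#' `exons_per_gene` exons, a 100 bp 5' UTR, a 3' UTR sized so the CDS length
#' is divisible by 3, and a random strand. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param gff3_path optional path: when given, the model is also written as
#'   GFF3 via [write_gff3()].
#' @return a [gene_model_set()].
#' @export
simulate_gene_models <- function(config, gff3_path = NULL) {
  set.seed(config$seed)
  chroms <- sim_chromosomes(config)
  chroms <- chroms[chroms$chrom != "Y", , drop = FALSE]
  gap <- 2 * config$flank + 3000
  cursors <- setNames(rep(gap, nrow(chroms)), chroms$chrom)
  genes <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    chrom <- chroms$chrom[((i - 1) %% nrow(chroms)) + 1]
    n_ex <- config$exons_per_gene
    ex_len <- sample(150:450, n_ex, replace = TRUE)
    in_len <- sample(600:2000, max(n_ex - 1, 0), replace = TRUE)
    start <- cursors[[chrom]]
    ex_start <- start + c(0, cumsum(ex_len[-n_ex] + in_len))
    exons <- data.frame(start = ex_start, end = ex_start + ex_len - 1)
    utr5 <- 100
    utr3 <- 150 + (sum(ex_len) - utr5 - 150) %% 3  # make CDS %% 3 == 0
    strand <- sample(c(1L, -1L), 1)
    genes[[i]] <- gene_model(
      gene_id = sprintf("gene%04d", i), chrom = chrom, strand = strand,
      exons = exons, gene_name = sprintf("GENE%04d", i),
      utr5_len = utr5, utr3_len = utr3)
    cursors[[chrom]] <- max(exons$end) + gap
    if (cursors[[chrom]] > chroms$length[chroms$chrom == chrom]) {
      stop("gene packing infeasible: chromosome ", chrom,
        " cannot hold its share of ", config$n_genes,
        " genes at the configured length; increase autosome_length or ",
        "reduce n_genes")
    }
  }
  gms <- gene_model_set(genes)
  if (!is.null(gff3_path)) write_gff3(gms, gff3_path)
  gms
}

#' Write a gene model set as GFF3
#'
#' Emits `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` features with `ID`/`Parent` attributes. Output bytes are
#' a deterministic function of the model.
#'
#' @param gms a [gene_model_set()].
#' @param path output path.
#' @export
write_gff3 <- function(gms, path) {
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, s, e, strand, attrs) {
    sprintf("%s\tsvcohort\t%s\t%d\t%d\t.\t%s\t.\t%s",
      chrom, type, s, e, if (strand > 0) "+" else "-", attrs)
  }
  for (g in gms$genes) {
    lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand,
      sprintf("ID=%s;Name=%s;biotype=%s", g$gene_id, g$gene_name, g$biotype)))
    for (tx in g$transcripts) {
      lines <- c(lines, fmt(g$chrom, "mRNA", min(tx$exons$start),
        max(tx$exons$end), g$strand,
        sprintf("ID=%s;Parent=%s", tx$transcript_id, g$gene_id)))
      emit <- function(iv, type) {
        if (is.null(iv) || nrow(iv) == 0) return(character(0))
        sprintf("%s\tsvcohort\t%s\t%d\t%d\t.\t%s\t%s\t%s",
          g$chrom, type, iv$start, iv$end,
          if (g$strand > 0) "+" else "-",
          if (type == "CDS") "0" else ".",
          sprintf("ID=%s.%s%d;Parent=%s", tx$transcript_id,
            tolower(type), seq_len(nrow(iv)), tx$transcript_id))
      }
      lines <- c(lines, emit(tx$exons, "exon"), emit(tx$cds, "CDS"),
        emit(tx$utr5, "five_prime_UTR"), emit(tx$utr3, "three_prime_UTR"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# draw a log-uniform SV length
.sim_length <- function(n, range) {
  round(exp(runif(n, log(range[1]), log(range[2]))))
}

# place one SV of a given type and target location class; returns
# list(chrom, start, end, length, location, gene) or NULL on failure
.place_sv <- function(type, class, genes, chroms, config) {
  is_ins <- type == "INS"
  if (is_ins && class == "exon_intron") class <- "intron"
  maxlen <- config$sv_length_range[2]
  if (class == "intergenic") {
    w <- chroms$length / sum(chroms$length)
    chrom <- sample(chroms$chrom, 1, prob = w)
    L <- .sim_length(1, config$sv_length_range)
    idx <- genes$index[genes$index$chrom == chrom, , drop = FALSE]
    for (try in 1:50) {
      s <- sample.int(chroms$length[chroms$chrom == chrom] - L - 1, 1)
      e <- if (is_ins) s else s + L
      clear <- nrow(idx) == 0 ||
        all(idx$start - (config$flank + 100) > e | idx$end + (config$flank + 100) < s)
      if (clear) {
        return(list(chrom = chrom, start = s, end = e, length = L,
          location = "intergenic", gene = ""))
      }
    }
    return(NULL)
  }
  g <- genes$genes[[sample(length(genes$genes), 1)]]
  tx <- g$transcripts[[1]]
  if (class == "exon") {
    cds <- tx$cds[tx$cds$end - tx$cds$start + 1 >= 64, , drop = FALSE]
    if (nrow(cds) == 0) return(NULL)
    row <- cds[sample(nrow(cds), 1), ]
    if (is_ins) {
      p <- sample(seq(row$start + 1, row$end - 1), 1)
      L <- .sim_length(1, c(50, 200))
      return(list(chrom = g$chrom, start = p, end = p, length = L,
        location = "exon", gene = g$gene_id))
    }
    L <- sample(50:min(maxlen, row$end - row$start - 6), 1)
    s <- sample(seq(row$start, row$end - L - 2), 1)
    return(list(chrom = g$chrom, start = s, end = s + L, length = L,
      location = "exon", gene = g$gene_id))
  }
  if (class == "utr") {
    iv <- rbind(tx$utr3, tx$utr5)
    iv <- iv[iv$end - iv$start + 1 >= 64, , drop = FALSE]
    if (is.null(iv) || nrow(iv) == 0) return(NULL)
    row <- iv[sample(nrow(iv), 1), ]
    if (is_ins) {
      p <- sample(seq(row$start + 1, row$end - 1), 1)
      L <- .sim_length(1, c(50, 200))
      return(list(chrom = g$chrom, start = p, end = p, length = L,
        location = "utr", gene = g$gene_id))
    }
    L <- sample(50:(row$end - row$start - 6), 1)
    s <- sample(seq(row$start, row$end - L - 2), 1)
    return(list(chrom = g$chrom, start = s, end = s + L, length = L,
      location = "utr", gene = g$gene_id))
  }
  if (class == "exon_intron") {
    intr <- .introns(tx)
    k <- sample(nrow(intr), 1)   # boundary between exon k and intron k (genomic)
    exw <- tx$exons$end[k] - tx$exons$start[k] + 1
    inw <- intr$end[k] - intr$start[k] + 1
    a <- sample(30:max(30, min(150, exw - 10)), 1)
    cc <- sample(30:max(30, min(300, inw - 10)), 1)
    b <- tx$exons$end[k]
    return(list(chrom = g$chrom, start = b - a, end = b + cc, length = a + cc,
      location = "exon_intron", gene = g$gene_id))
  }
  if (class == "intron") {
    intr <- .introns(tx)
    intr <- intr[intr$end - intr$start + 1 >= 120, , drop = FALSE]
    if (nrow(intr) == 0) return(NULL)
    row <- intr[sample(nrow(intr), 1), ]
    if (is_ins) {
      p <- sample(seq(row$start + 13, row$end - 13), 1)
      L <- .sim_length(1, c(50, 200))
      return(list(chrom = g$chrom, start = p, end = p, length = L,
        location = "intron", gene = g$gene_id))
    }
    L <- sample(50:min(maxlen, row$end - row$start - 28), 1)
    s <- sample(seq(row$start + 12, row$end - L - 13), 1)
    return(list(chrom = g$chrom, start = s, end = s + L, length = L,
      location = "intron", gene = g$gene_id))
  }
  if (class == "upstream_downstream") {
    L <- sample(50:min(maxlen, config$flank - 400), 1)
    d1 <- sample(100:(config$flank - L - 150), 1)
    if (runif(1) < 0.5) {            # downstream of the gene span
      s <- g$end + d1
      e <- if (is_ins) s else s + L
    } else {
      e <- g$start - d1
      s <- if (is_ins) e else e - L
      if (is_ins) s <- e
    }
    return(list(chrom = g$chrom, start = s, end = e, length = L,
      location = "upstream_downstream", gene = g$gene_id))
  }
  NULL
}

#' Plant a synthetic cohort of true SVs
#'
#' Shared SVs draw carriers across all groups (at least two groups
#' represented); group-specific SVs draw at least two carriers confined to
#' one group. Positions are stratified over location classes per
#' `location_mix`, and no two planted SVs of the same type overlap (with a
#' 200 bp guard band), keeping the ground truth unambiguous under the merge
#' rule. `specific_to` is derived from the realised carrier sets.
#'
#' @param config a [sim_config()].
#' @param genes a [gene_model_set()] from [simulate_gene_models()].
#' @return truth data.frame with columns `sv_id`, `chrom`, `start`, `end`,
#'   `svtype`, `length`, `planted_as`, `specific_to`, `n_carriers`,
#'   `carriers`, `location`, `gene`.
#' @export
simulate_cohort <- function(config, genes) {
  set.seed(config$seed + 1L)
  chroms <- sim_chromosomes(config)
  sheet <- sim_sample_sheet(config)
  intents <- c(rep("shared", config$n_shared_svs),
    rep(names(config$n_specific_svs), config$n_specific_svs))
  n <- length(intents)
  types <- sample(names(config$type_mix), n, replace = TRUE,
    prob = config$type_mix)
  classes <- sample(names(config$location_mix), n, replace = TRUE,
    prob = config$location_mix)
  occupied <- list()  # per chrom\rtype: matrix of (start, end)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- NULL
    for (try in 1:200) {
      cand <- .place_sv(types[i], classes[i], genes, chroms, config)
      if (is.null(cand)) next
      key <- paste(cand$chrom, types[i], sep = "\r")
      occ <- occupied[[key]]
      pad <- 200
      clash <- !is.null(occ) &&
        any(occ[, 1] - pad <= cand$end & occ[, 2] + pad >= cand$start)
      if (!clash) {
        occupied[[key]] <- rbind(occ, c(cand$start, cand$end))
        placed <- cand
        break
      }
    }
    if (is.null(placed)) {
      stop("could not place planted SV ", i, " after 200 attempts; ",
        "the simulated genome is too crowded for the configured SV count")
    }
    # carriers
    freq <- runif(1, config$carrier_freq_range[1], config$carrier_freq_range[2])
    if (intents[i] == "shared") {
      repeat {
        take <- rbinom(nrow(sheet), 1, freq) == 1
        if (sum(take) >= 2 && length(unique(sheet$group[take])) >= 2) break
      }
      carriers <- sheet$sample_id[take]
    } else {
      members <- sheet$sample_id[sheet$group == intents[i]]
      repeat {
        take <- rbinom(length(members), 1, freq) == 1
        if (sum(take) >= 2) break
      }
      carriers <- members[take]
    }
    carrier_groups <- unique(sheet$group[sheet$sample_id %in% carriers])
    rows[[i]] <- data.frame(
      sv_id = sprintf("t_%04d", i), chrom = placed$chrom,
      start = placed$start, end = placed$end, svtype = types[i],
      length = placed$length, planted_as = intents[i],
      specific_to = if (length(carrier_groups) == 1) carrier_groups else NA_character_,
      n_carriers = length(carriers),
      carriers = paste(sort(carriers), collapse = ","),
      location = placed$location, gene = placed$gene,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  truth
}

#' Simulate one caller's output over the planted cohort
#'
#' For every sample and every planted SV it carries, the call is emitted with
#' probability `1 - fn_rate`, its breakpoints independently perturbed by
#' rounded zero-mean Gaussian jitter (length recomputed from the jittered
#' breakpoints for span types), and a support count drawn from the support
#' distribution. False positives are scattered uniformly over the genome at
#' `fp_per_mb` per Mb with random types and lengths, independently across
#' callers. Deterministic given (`config$seed`, `caller_id`).
#'
#' @param truth truth table from [simulate_cohort()].
#' @param config the [sim_config()].
#' @param caller_id caller name (e.g. `"callerA"`).
#' @param dir optional output directory: per-sample normalized caller TSVs
#'   are written to `dir/<caller_id>/<sample_id>.tsv`.
#' @param seed RNG seed; defaults to a deterministic function of
#'   `config$seed` and `caller_id`.
#' @return data.frame of calls (`caller_id`, `sample_id`, `chrom`, `start`,
#'   `end`, `svtype`, `length`, `support`, `truth_id` — NA for false
#'   positives).
#' @export
simulate_caller_output <- function(truth, config, caller_id, dir = NULL,
                                   seed = NULL) {
  if (is.null(seed)) {
    seed <- (config$seed * 1009L + sum(utf8ToInt(caller_id)) * 131L) %% .Machine$integer.max
  }
  set.seed(seed)
  chroms <- sim_chromosomes(config)
  sheet <- sim_sample_sheet(config)
  genome_mb <- sum(chroms$length) / 1e6
  carrier_list <- strsplit(truth$carriers, ",", fixed = TRUE)
  draw_support <- function(n) {
    config$support_min + rpois(n, max(0, config$support_mean - config$support_min))
  }
  out <- vector("list", nrow(sheet))
  for (si in seq_len(nrow(sheet))) {
    sample_id <- sheet$sample_id[si]
    carried <- which(vapply(carrier_list, function(cs) sample_id %in% cs, logical(1)))
    detected <- carried[runif(length(carried)) >= config$fn_rate]
    tp <- NULL
    if (length(detected) > 0) {
      s <- truth$start[detected] + round(rnorm(length(detected), 0, config$jitter_sd))
      e <- truth$end[detected] + round(rnorm(length(detected), 0, config$jitter_sd))
      s <- pmax(s, 1L)
      ins <- truth$svtype[detected] == "INS"
      e[ins] <- s[ins]                      # insertions stay zero-width points
      e[!ins] <- pmax(e[!ins], s[!ins] + 1L)  # guard against jitter collapse
      tp <- data.frame(chrom = truth$chrom[detected], start = s, end = e,
        svtype = truth$svtype[detected],
        length = ifelse(ins, truth$length[detected], e - s),
        support = draw_support(length(detected)),
        truth_id = truth$sv_id[detected], stringsAsFactors = FALSE)
    }
    n_fp <- rpois(1, config$fp_per_mb * genome_mb)
    fp <- NULL
    if (n_fp > 0) {
      fchrom <- sample(chroms$chrom, n_fp, replace = TRUE,
        prob = chroms$length / sum(chroms$length))
      flen <- .sim_length(n_fp, config$sv_length_range)
      ftype <- sample(names(config$type_mix), n_fp, replace = TRUE,
        prob = config$type_mix)
      fstart <- vapply(seq_len(n_fp), function(k) {
        sample.int(chroms$length[chroms$chrom == fchrom[k]] - flen[k] - 1, 1)
      }, integer(1))
      fins <- ftype == "INS"
      fp <- data.frame(chrom = fchrom, start = fstart,
        end = ifelse(fins, fstart, fstart + flen), svtype = ftype,
        length = flen, support = draw_support(n_fp),
        truth_id = NA_character_, stringsAsFactors = FALSE)
    }
    calls <- rbind(tp, fp)
    if (is.null(calls)) {
      calls <- data.frame(chrom = character(0), start = integer(0),
        end = integer(0), svtype = character(0), length = integer(0),
        support = integer(0), truth_id = character(0), stringsAsFactors = FALSE)
    }
    calls <- cbind(caller_id = caller_id, sample_id = sample_id, calls,
      stringsAsFactors = FALSE)
    out[[si]] <- calls
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(dir)) {
    subdir <- file.path(dir, caller_id)
    dir.create(subdir, recursive = TRUE, showWarnings = FALSE)
    for (sample_id in sheet$sample_id) {
      sel <- out[out$sample_id == sample_id,
        c("chrom", "start", "end", "svtype", "length", "support"), drop = FALSE]
      write.table(sel, file.path(subdir, paste0(sample_id, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' Simulate gene sets and an aging-gene list for the candidate screen
#'
#' Builds random background terms plus a few terms tagged `skin aging` whose
#' members are seeded with genes hit by planted group-specific SVs, and an
#' aging-gene list drawn the same way — the synthetic analogue of curated
#' pathway and literature resources.
#'
#' @param truth truth table from [simulate_cohort()].
#' @param genes the [gene_model_set()].
#' @param config the [sim_config()].
#' @param n_random_terms number of untagged background terms.
#' @param n_tagged_terms number of `skin aging`-tagged terms.
#' @return list with `gene_sets` (GMT-style list) and `aging_genes`
#'   (character vector).
#' @export
simulate_gene_sets <- function(truth, genes, config, n_random_terms = 30,
                               n_tagged_terms = 3) {
  set.seed(config$seed + 2L)
  background <- genes$index$gene_id
  hit <- unique(truth$gene[!is.na(truth$specific_to) & nzchar(truth$gene)])
  sets <- list()
  for (k in seq_len(n_tagged_terms)) {
    core <- if (length(hit) > 0) {
      sample(hit, max(1, ceiling(length(hit) / 2)))
    } else character(0)
    fill <- sample(setdiff(background, core),
      max(0, 25 - length(core)))
    sets[[length(sets) + 1]] <- list(
      term_id = sprintf("TERM_SKIN_%02d", k),
      term_name = sprintf("skin aging structure set %d", k),
      genes = unique(c(core, fill)))
  }
  for (k in seq_len(n_random_terms)) {
    sets[[length(sets) + 1]] <- list(
      term_id = sprintf("TERM_RAND_%02d", k),
      term_name = sprintf("random background set %d", k),
      genes = sample(background, sample(10:40, 1)))
  }
  aging <- unique(c(
    if (length(hit) > 0) sample(hit, max(1, ceiling(length(hit) / 3))),
    sample(background, 10)))
  list(gene_sets = sets, aging_genes = aging)
}
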