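#' Run the full cohort SV pipeline
#'
#' Executes simulate (optional) -> read -> per-sample dual-caller consensus ->
#' cross-individual merge -> cohort filters -> annotation -> group-specific
#' screen -> PCA and allele-frequency tests -> enrichment -> candidate
#' screen, writing every artifact table plus a run manifest to `out_dir`.
#'
#' `config` is a YAML file path or an equivalent nested list with blocks:
#' \describe{
#'   \item{seed}{integer; seeds the simulator when used.}
#'   \item{simulate}{optional; overrides passed to [sim_config()]. When
#'     present, all inputs are generated (and written under
#'     `out_dir/inputs/`).}
#'   \item{inputs}{otherwise required: `calls_dir` (with
#'     `<caller>/<sample>.tsv` tables), `callers` (two ids), `sample_sheet`,
#'     `gff3`, and optionally `gene_sets` (GMT) and `aging_genes` (one per
#'     line).}
#'   \item{params}{thresholds: `min_support` (3), `min_overlap` (25),
#'     `ins_window` (25), `min_individuals` (2), `drop_chroms` ("Y"),
#'     `flank` (5000), `target_group`, `alpha` (0.05).}
#' }
#'
#' @param config YAML path or list.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main result tables (`cohort`,
#'   `annotations`, `specific`, `pca`, `af_test`, `enrichment`,
#'   `candidates`) and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  get <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default
  min_support <- get("min_support", 3)
  min_overlap <- get("min_overlap", 25)
  ins_window <- get("ins_window", 25)
  min_individuals <- get("min_individuals", 2)
  drop_chroms <- unlist(get("drop_chroms", "Y"))
  flank <- get("flank", 5000)
  alpha <- get("alpha", 0.05)
  seed <- if (!is.null(config$seed)) config$seed else 1L

  manifest <- list(
    tool = "svcohort",
    version = as.character(packageVersion("svcohort")),
    seed = seed,
    config = config,
    inputs = list(),
    stages = list())
  tsv <- function(x, name) {
    path <- file.path(out_dir, name)
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  # ---- inputs: simulated or read from disk -------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    # YAML parses named vectors as lists; flatten them back
    sim_args <- lapply(sim_args, function(x) if (is.list(x)) unlist(x) else x)
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    in_dir <- file.path(out_dir, "inputs")
    dir.create(in_dir, showWarnings = FALSE)
    genes <- simulate_gene_models(cfg, gff3_path = file.path(in_dir, "genes.gff3"))
    truth <- simulate_cohort(cfg, genes)
    tsv(truth, file.path("inputs", "truth.tsv"))
    sheet <- sim_sample_sheet(cfg)
    tsv(sheet, file.path("inputs", "sample_sheet.tsv"))
    callers <- c("callerA", "callerB")
    calls <- lapply(callers, function(cid) {
      simulate_caller_output(truth, cfg, cid, dir = file.path(in_dir, "calls"))
    })
    names(calls) <- callers
    gs <- simulate_gene_sets(truth, genes, cfg)
    write_gmt(gs$gene_sets, file.path(in_dir, "gene_sets.gmt"))
    writeLines(gs$aging_genes, file.path(in_dir, "aging_genes.txt"))
    gene_sets <- gs$gene_sets
    aging_genes <- gs$aging_genes
    flank <- cfg$flank
    target_group <- get("target_group", names(cfg$group_sizes)[1])
  } else {
    inp <- config$inputs
    if (is.null(inp$sample_sheet) || !file.exists(inp$sample_sheet)) {
      stop("config$inputs$sample_sheet is missing or does not exist")
    }
    if (is.null(inp$calls_dir) || is.null(inp$callers) ||
        length(inp$callers) != 2) {
      stop("config$inputs needs calls_dir and exactly two callers")
    }
    sheet <- read_sample_sheet(inp$sample_sheet)
    callers <- unlist(inp$callers)
    calls <- lapply(callers, function(cid) {
      files <- file.path(inp$calls_dir, cid, paste0(sheet$sample_id, ".tsv"))
      do.call(rbind, lapply(seq_along(files), function(i) {
        read_caller_calls(files[i], cid, sheet$sample_id[i])
      }))
    })
    names(calls) <- callers
    genes <- read_gene_models(inp$gff3)
    gene_sets <- if (!is.null(inp$gene_sets)) read_gmt(inp$gene_sets) else list()
    aging_genes <- if (!is.null(inp$aging_genes)) {
      read_gene_list(inp$aging_genes)
    } else character(0)
    truth <- NULL
    for (f in c(inp$sample_sheet, inp$gff3, inp$gene_sets, inp$aging_genes)) {
      manifest$inputs[[basename(f)]] <- unname(tools::md5sum(f))
    }
    target_group <- get("target_group", sheet$group[1])
  }

  # ---- consensus and merge ----------------------------------------------
  raw_counts <- vapply(calls, nrow, integer(1))
  consensus <- do.call(rbind, lapply(sheet$sample_id, function(sid) {
    dual_caller_consensus(
      calls[[1]][calls[[1]]$sample_id == sid, , drop = FALSE],
      calls[[2]][calls[[2]]$sample_id == sid, , drop = FALSE],
      min_support = min_support, min_overlap = min_overlap,
      ins_window = ins_window)
  }))
  merged <- merge_cohort(consensus, min_overlap = min_overlap,
    ins_window = ins_window)
  cohort <- apply_cohort_filters(merged, min_individuals = min_individuals,
    drop_chroms = drop_chroms)
  flog <- attr(cohort, "filter_log")
  manifest$stages <- list(
    raw_calls = as.list(raw_counts),
    consensus_calls = nrow(consensus),
    merged_svs = nrow(merged),
    removed_chrom = unname(flog[["removed_chrom"]]),
    removed_min_individuals = unname(flog[["removed_min_individuals"]]),
    cohort_svs = nrow(cohort))
  tsv(cohort, "cohort.tsv")
  export_vcf(cohort, sheet$sample_id, file.path(out_dir, "cohort.vcf"))

  # ---- annotation --------------------------------------------------------
  annotations <- annotate_svs(cohort, genes, flank = flank)
  tsv(annotations, "annotations.tsv")
  tsv(location_summary(annotations), "location_summary.tsv")

  # ---- cohort comparisons ------------------------------------------------
  gm <- build_genotype_matrix(cohort, sheet)
  tsv(data.frame(sample_id = rownames(gm), as.data.frame(gm),
    check.names = FALSE), "genotype_matrix.tsv")
  specific <- find_group_specific(gm, target_group)
  tsv(specific, "group_specific.tsv")
  tsv(attr(specific, "venn"), "venn_counts.tsv")
  cd <- chrom_distribution(cohort)
  tsv(data.frame(chrom = names(cd), n_svs = as.integer(cd)), "chrom_counts.tsv")
  pca <- pca_genotypes(gm, n_components = min(3, nrow(gm) - 1))
  groups <- attr(gm, "groups")[rownames(gm)]
  tsv(data.frame(sample_id = rownames(pca$scores), group = groups,
    pca$scores, check.names = FALSE), "pca.tsv")
  af <- allele_frequency_test(gm, adjust = TRUE, alpha = alpha)
  tsv(af, "allele_frequency_tests.tsv")

  # ---- enrichment and candidate screen -----------------------------------
  spec_ids <- specific$sv_id[specific$specific]
  spec_svs <- cohort[match(spec_ids, cohort$id), , drop = FALSE]
  spec_ann <- annotations[match(spec_ids, annotations$sv_id), , drop = FALSE]
  spec_genes <- unique(unlist(strsplit(spec_ann$genes, ",", fixed = TRUE)))
  spec_genes <- spec_genes[nzchar(spec_genes)]
  background <- genes$index$gene_id
  enrichment <- if (length(gene_sets) > 0 && length(spec_genes) > 0) {
    hypergeometric_enrichment(intersect(spec_genes, background),
      gene_sets, background)
  } else {
    data.frame(term_id = character(0), term_name = character(0),
      k = integer(0), n = integer(0), K = integer(0), N = integer(0),
      p = numeric(0), overlap_genes = character(0))
  }
  tsv(enrichment, "enrichment.tsv")
  candidates <- screen_candidates(spec_svs, spec_ann, enrichment,
    aging_genes = aging_genes, alpha = alpha)
  tsv(candidates, "candidates.tsv")
  manifest$stages$specific_svs <- length(spec_ids)
  manifest$stages$enriched_terms <- sum(enrichment$p < alpha)
  manifest$stages$candidate_pairs <- nrow(candidates)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, annotations = annotations,
    specific = specific, pca = pca, af_test = af, enrichment = enrichment,
    candidates = candidates, manifest = manifest,
    truth = truth, genotype_matrix = gm))
}
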