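# a small, fast configuration used by most simulator unit tests
small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_autosomes = 3, autosome_length = 4e6,
    sex_chrom_length = 2e6, n_genes = 45,
    n_shared_svs = 60, n_specific_svs = c(WXP = 15, XP = 8, EUP = 8))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("gene model simulation is deterministic and structurally valid", {
  cfg <- small_cfg(seed = 9)
  p1 <- withr::local_tempfile(fileext = ".gff3")
  p2 <- withr::local_tempfile(fileext = ".gff3")
  simulate_gene_models(cfg, gff3_path = p1)
  simulate_gene_models(cfg, gff3_path = p2)
  expect_identical(readLines(p1), readLines(p2))   # byte-identical

  gms <- simulate_gene_models(cfg)
  expect_length(gms$genes, cfg$n_genes)
  for (g in gms$genes) {
    tx <- g$transcripts[[1]]
    # exons ordered, non-overlapping
    expect_true(all(diff(tx$exons$start) > 0))
    expect_true(all(tx$exons$start[-1] > tx$exons$end[-nrow(tx$exons)]))
    # CDS length divisible by 3 and contained in exons
    expect_equal(sum(tx$cds$end - tx$cds$start + 1) %% 3, 0)
    cds_ir <- IRanges::IRanges(tx$cds$start, tx$cds$end)
    ex_ir <- IRanges::IRanges(tx$exons$start, tx$exons$end)
    expect_equal(sum(IRanges::width(IRanges::setdiff(cds_ir, ex_ir))), 0)
  }
  # genes far enough apart that annotation flanks never collide
  idx <- gms$index[order(gms$index$chrom, gms$index$start), ]
  for (ch in unique(idx$chrom)) {
    sub <- idx[idx$chrom == ch, ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$start[-1] - sub$end[-nrow(sub)] > 2 * cfg$flank))
    }
  }
  # zero genes is a valid empty model
  empty <- simulate_gene_models(small_cfg(n_genes = 0))
  expect_length(empty$genes, 0)
})

test_that("planted cohorts respect carrier and overlap constraints", {
  cfg <- small_cfg(seed = 4)
  gms <- simulate_gene_models(cfg)
  truth <- simulate_cohort(cfg, gms)
  expect_equal(nrow(truth), cfg$n_shared_svs + sum(cfg$n_specific_svs))
  expect_identical(truth, simulate_cohort(cfg, gms))  # reproducible draws
  # planted counts per intent
  expect_equal(sum(truth$planted_as == "WXP"), 15)
  # specific SVs always have >= 2 carriers, all within the planted group
  spec <- truth[truth$planted_as != "shared", ]
  expect_true(all(spec$n_carriers >= 2))
  expect_equal(spec$specific_to, spec$planted_as)
  # shared SVs span at least two groups, hence are never specific
  expect_true(all(is.na(truth$specific_to[truth$planted_as == "shared"])))
  # same-type planted SVs never overlap (truth stays unambiguous when merged)
  for (key in unique(paste(truth$chrom, truth$svtype))) {
    sub <- truth[paste(truth$chrom, truth$svtype) == key, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
    }
  }
  # every location class is represented
  expect_setequal(unique(truth$location),
    c("intron", "intergenic", "upstream_downstream", "exon", "exon_intron", "utr"))
})

test_that("noiseless callers reproduce exactly the carried truth records", {
  cfg <- small_cfg(seed = 6, jitter_sd = 0, fn_rate = 0, fp_per_mb = 0)
  gms <- simulate_gene_models(cfg)
  truth <- simulate_cohort(cfg, gms)
  calls <- simulate_caller_output(truth, cfg, "callerA")
  expect_true(all(!is.na(calls$truth_id)))          # no false positives
  # one call per (carrier, SV) pair with exact coordinates
  expected <- sum(truth$n_carriers)
  expect_equal(nrow(calls), expected)
  m <- match(calls$truth_id, truth$sv_id)
  expect_equal(calls$start, truth$start[m])
  expect_equal(calls$end, truth$end[m])
  expect_equal(calls$length, truth$length[m])
  expect_true(all(calls$support >= cfg$support_min))
})

test_that("caller output is deterministic per caller and passes validation", {
  cfg <- small_cfg(seed = 2)
  gms <- simulate_gene_models(cfg)
  truth <- simulate_cohort(cfg, gms)
  a1 <- simulate_caller_output(truth, cfg, "callerA")
  a2 <- simulate_caller_output(truth, cfg, "callerA")
  b1 <- simulate_caller_output(truth, cfg, "callerB")
  expect_identical(a1, a2)
  expect_false(identical(a1$start, b1$start))  # independent noise per caller
  expect_silent(validate_sv_calls(a1))
  # per-sample TSVs use the normalized caller dialect
  dir <- withr::local_tempdir()
  simulate_caller_output(truth, cfg, "callerA", dir = dir)
  sheet <- sim_sample_sheet(cfg)
  f <- file.path(dir, "callerA", paste0(sheet$sample_id[1], ".tsv"))
  expect_true(file.exists(f))
  back <- read_caller_calls(f, "callerA", sheet$sample_id[1])
  expect_gt(nrow(back), 0)
})

test_that("dual-caller consensus suppresses independent false positives", {
  cfg <- small_cfg(seed = 8, fp_per_mb = 5, fn_rate = 0.1)
  gms <- simulate_gene_models(cfg)
  truth <- simulate_cohort(cfg, gms)
  ca <- simulate_caller_output(truth, cfg, "callerA")
  cb <- simulate_caller_output(truth, cfg, "callerB")
  raw_fp_rate <- mean(is.na(ca$truth_id))
  sheet <- sim_sample_sheet(cfg)
  cons <- do.call(rbind, lapply(sheet$sample_id, function(sid) {
    dual_caller_consensus(ca[ca$sample_id == sid, ], cb[cb$sample_id == sid, ])
  }))
  # a consensus record is a false positive when no planted SV explains it
  cons_fp <- vapply(seq_len(nrow(cons)), function(i) {
    tr <- truth[truth$svtype == cons$svtype[i] & truth$chrom == cons$chrom[i], ]
    if (cons$svtype[i] == "INS") {
      !any(abs(tr$start - cons$start[i]) <= 25)
    } else {
      !any(pmin(tr$end, cons$end[i]) - pmax(tr$start, cons$start[i]) > 25)
    }
  }, logical(1))
  expect_lt(mean(cons_fp), raw_fp_rate)
})

test_that("zero-noise pipeline recovers the planted group structure exactly", {
  cfg <- small_cfg(seed = 12, jitter_sd = 0, fn_rate = 0, fp_per_mb = 0)
  run <- run_sim_pipeline(cfg)
  gm <- build_genotype_matrix(run$cohort, run$sheet)
  spec <- find_group_specific(gm, "WXP")
  stats <- recovery_stats(run$truth, run$ca, run$cb, run$cohort,
    specific = spec, target_group = "WXP")
  expect_equal(stats$merged_once_rate, 1)
  expect_equal(stats$specific_recovery_rate, 1)
  expect_equal(stats$n_false_specific, 0)
  # truth-conditional annotation accuracy at zero jitter
  ann <- annotate_svs(run$cohort, run$genes)
  m <- vapply(seq_len(nrow(run$truth)), function(i) {
    tr <- run$truth[i, ]
    if (tr$chrom %in% "Y") return(NA_character_)
    same <- run$cohort$svtype == tr$svtype & run$cohort$chrom == tr$chrom &
      run$cohort$start == tr$start & run$cohort$end == tr$end
    if (!any(same)) return(NA_character_)
    ann$location[match(run$cohort$id[same][1], ann$sv_id)]
  }, character(1))
  ok <- !is.na(m)
  expect_gte(mean(m[ok] == run$truth$location[ok]), 0.99)
})
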