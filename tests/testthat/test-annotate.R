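toy_set <- function(...) gene_model_set(list(toy_gene(...)))

sv_row <- function(start, end, svtype = "DEL", chrom = "1", id = "sv_00001") {
  data.frame(id = id, chrom = chrom, start = start, end = end,
    svtype = svtype,
    length = if (svtype == "INS") 60L else end - start,
    stringsAsFactors = FALSE)
}

test_that("location classes follow the documented precedence on a toy gene", {
  gs <- toy_set()
  expect_equal(classify_location(sv_row(150, 180), gs)$location, "exon")
  expect_equal(classify_location(sv_row(150, 180), gs)$location_string,
    "EXON=1/2,STRAND=1")
  ann <- classify_location(sv_row(190, 250), gs)
  expect_equal(ann$location, "exon_intron")
  expect_equal(ann$location_string, "EXON=1/2,INTRON=1/1,STRAND=1")
  expect_equal(classify_location(sv_row(210, 290), gs)$location, "intron")
  updown <- classify_location(sv_row(600, 700), gs)
  expect_equal(updown$location, "upstream_downstream")
  expect_equal(updown$distance, 200)  # 600 - gene end 400
  expect_equal(classify_location(sv_row(9000, 9100), gs)$location, "intergenic")
  expect_equal(classify_location(sv_row(9000, 9100), gs)$genes, "")
})

test_that("UTR-only overlap classifies as utr, coding overlap as exon", {
  gs <- toy_set(utr5 = 50, utr3 = 60)  # utr5: 100-149; utr3: 341-400
  expect_equal(classify_location(sv_row(341, 395), gs)$location, "utr")
  expect_equal(classify_location(sv_row(150, 200), gs)$location, "exon")
  # insertions are points
  expect_equal(classify_location(sv_row(350, 350, "INS"), gs)$location, "utr")
  expect_equal(classify_location(sv_row(160, 160, "INS"), gs)$location, "exon")
})

test_that("exon ordinals are strand-aware and reversal maps i to n-i+1", {
  plus <- gene_model_set(list(toy_gene(strand = 1L)))
  minus <- gene_model_set(list(toy_gene(strand = -1L)))
  sv <- sv_row(150, 180)
  expect_equal(classify_location(sv, plus)$location_string, "EXON=1/2,STRAND=1")
  expect_equal(classify_location(sv, minus)$location_string, "EXON=2/2,STRAND=-1")
  expect_equal(classify_location(sv, plus)$location,
    classify_location(sv, minus)$location)
})

test_that("published-style location strings are reproduced from matching layouts", {
  # intronic deletion in intron 3 of a 8-exon plus-strand gene -> INTRON=3/7
  g1 <- gene_model_set(list(uniform_gene(8, strand = 1L)))
  iv3 <- 10000 + 3 * 1200 - 1000  # inside genomic intron 3
  ann <- classify_location(sv_row(iv3 + 100, iv3 + 160), g1)
  expect_equal(ann$location_string, "INTRON=3/7,STRAND=1")

  # minus-strand gene, 16 exons: deletion spanning the genomic boundary of
  # exon 10 / intron 10 reads as exon 7 / intron 6 along the transcript
  g2 <- gene_model_set(list(uniform_gene(16, strand = -1L)))
  boundary <- 10000 + 9 * 1200 + 199   # end of genomic exon 10
  ann2 <- classify_location(sv_row(boundary - 40, boundary + 49), g2)
  expect_equal(ann2$location_string, "EXON=7/16,INTRON=6/15,STRAND=-1")

  # deletion confined to the last exon of a plus-strand 37-exon gene
  g3 <- gene_model_set(list(uniform_gene(37, strand = 1L)))
  last_start <- 10000 + 36 * 1200
  ann3 <- classify_location(sv_row(last_start + 20, last_start + 150), g3)
  expect_equal(ann3$location_string, "EXON=37/37,STRAND=1")
})

test_that("impact rules rank stop-loss and frameshift above splice and intron effects", {
  # 89 bp deletion fully inside coding sequence: 89 %% 3 == 2 -> frameshift
  g <- gene_model_set(list(uniform_gene(8, strand = 1L, exon_len = 300L)))
  cds_mid <- 10000 + 2 * 1300 + 100
  sv <- sv_row(cds_mid, cds_mid + 89)
  ann <- annotate_svs(sv, g)
  expect_equal(ann$location, "exon")
  expect_match(ann$consequences, "frameshift")
  expect_equal(ann$impact, "high")

  # deletion covering the stop codon (last coding bases) and the 3' UTR
  gstop <- gene_model_set(list(uniform_gene(4, strand = 1L, exon_len = 300L)))
  tx <- gstop$genes[[1]]$transcripts[[1]]
  stop_end <- max(tx$cds$end)
  sv2 <- sv_row(stop_end - 10, stop_end + 30)
  ann2 <- annotate_svs(sv2, gstop)
  expect_match(ann2$consequences, "stop_lost")
  expect_equal(ann2$impact, "high")

  # 60 bp deletion deep inside an intron: modifier intron variant
  deep <- 10000 + 200 + 400  # 400 bp into genomic intron 1 (1000 bp)
  ann3 <- annotate_svs(sv_row(deep, deep + 60), g)
  expect_equal(ann3$location, "intron")
  expect_equal(ann3$consequences, "intron_variant")
  expect_equal(ann3$impact, "modifier")

  # boundary-spanning deletion is a splice-region modifier unless frameshifting
  b <- 10000 + 299  # end of exon 1
  ann4 <- annotate_svs(sv_row(b - 30, b + 60), g)
  expect_equal(ann4$location, "exon_intron")
  expect_match(ann4$consequences, "splice_region")

  # flanking and intergenic records
  gs <- toy_set()
  ann5 <- annotate_svs(sv_row(600, 700), gs)
  expect_equal(ann5$consequences, "regulatory_region")
  expect_equal(ann5$impact, "modifier")
  ann6 <- annotate_svs(sv_row(9000, 9100), gs)
  expect_equal(ann6$consequences, "intergenic_variant")
  expect_equal(ann6$impact, "none")
})

test_that("an unknown chromosome warns and falls back to intergenic", {
  gs <- toy_set()
  expect_warning(ann <- classify_location(sv_row(100, 200, chrom = "99"), gs),
    "absent from the gene model")
  expect_equal(ann$location, "intergenic")
})

test_that("location summaries count every SV once with half-up percentages", {
  ann <- data.frame(location = rep(c("intron", "intergenic", "exon"), c(5, 3, 2)))
  s <- location_summary(ann)
  expect_equal(sum(s$count), 10)
  expect_equal(s$percent[s$location == "intron"], 50)
  one <- location_summary(data.frame(location = rep("intron", 7)))
  expect_equal(one$percent[one$location == "intron"], 100)
  expect_equal(nrow(location_summary(ann[0, , drop = FALSE])), 0)
})

test_that("gene models round-trip through GFF3", {
  cfg <- sim_config(seed = 3, n_genes = 8, n_autosomes = 2,
    autosome_length = 2e6, include_sex_chroms = FALSE)
  path <- withr::local_tempfile(fileext = ".gff3")
  gms <- simulate_gene_models(cfg, gff3_path = path)
  back <- read_gene_models(path)
  expect_equal(back$index$gene_id, gms$index$gene_id)
  expect_equal(back$index$start, gms$index$start)
  expect_equal(back$index$strand, gms$index$strand)
  for (gid in gms$index$gene_id) {
    expect_equal(back$genes[[gid]]$transcripts[[1]]$exons,
      gms$genes[[gid]]$transcripts[[1]]$exons)
    expect_equal(back$genes[[gid]]$transcripts[[1]]$cds,
      gms$genes[[gid]]$transcripts[[1]]$cds)
  }
})
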