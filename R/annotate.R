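#' Construct a gene model
#'
#' Builds one gene with a single transcript from genomic exon intervals.
#' Exons are stored left-to-right in genomic coordinates; exon/intron
#' ordinals are reported strand-aware (exon 1 is the 5'-most exon, so on the
#' minus strand it is the genomically rightmost one). The coding sequence is
#' the exonic sequence minus the two UTRs, which sit at the transcript's ends.
#'
#' @param gene_id,gene_name identifiers.
#' @param chrom chromosome name.
#' @param strand `+1` or `-1`.
#' @param exons data.frame with `start`, `end` (1-based inclusive, genomic
#'   order, non-overlapping).
#' @param utr5_len,utr3_len lengths in bp of the 5' and 3' UTRs, measured
#'   along the transcript from its ends; may be 0.
#' @param biotype one of `"protein_coding"`, `"pseudogene"`, `"noncoding"`.
#' @return a `gene_model` list with elements `gene_id`, `gene_name`,
#'   `biotype`, `chrom`, `strand`, `start`, `end`, `transcripts`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, gene_name = gene_id,
                       utr5_len = 0, utr3_len = 0, biotype = "protein_coding") {
  stopifnot(strand %in% c(1L, -1L, 1, -1))
  exons <- data.frame(start = as.integer(exons$start),
    end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons must be non-overlapping")
  }
  total_exonic <- sum(exons$end - exons$start + 1)
  if (utr5_len + utr3_len >= total_exonic && biotype == "protein_coding") {
    stop("UTRs leave no coding sequence")
  }
  # carve UTRs out of the exon chain along the transcript direction
  left_len <- if (strand > 0) utr5_len else utr3_len   # at the genomic left end
  right_len <- if (strand > 0) utr3_len else utr5_len
  carve_left <- function(len) {
    iv <- NULL; remaining <- len
    for (k in seq_len(nrow(exons))) {
      if (remaining <= 0) break
      take <- min(remaining, exons$end[k] - exons$start[k] + 1)
      iv <- rbind(iv, data.frame(start = exons$start[k],
        end = exons$start[k] + take - 1))
      remaining <- remaining - take
    }
    iv
  }
  carve_right <- function(len) {
    iv <- NULL; remaining <- len
    for (k in rev(seq_len(nrow(exons)))) {
      if (remaining <= 0) break
      take <- min(remaining, exons$end[k] - exons$start[k] + 1)
      iv <- rbind(data.frame(start = exons$end[k] - take + 1,
        end = exons$end[k]), iv)
      remaining <- remaining - take
    }
    iv
  }
  left_utr <- carve_left(left_len)
  right_utr <- carve_right(right_len)
  cds <- if (biotype == "protein_coding") {
    ir <- IRanges::IRanges(exons$start, exons$end)
    drop <- IRanges::IRanges(
      c(if (!is.null(left_utr)) left_utr$start, if (!is.null(right_utr)) right_utr$start),
      c(if (!is.null(left_utr)) left_utr$end, if (!is.null(right_utr)) right_utr$end))
    res <- IRanges::setdiff(ir, drop)
    data.frame(start = IRanges::start(res), end = IRanges::end(res))
  } else NULL
  tx <- list(
    transcript_id = paste0(gene_id, ".t1"),
    exons = exons[, c("start", "end")],
    cds = cds,
    utr5 = if (strand > 0) left_utr else right_utr,
    utr3 = if (strand > 0) right_utr else left_utr)
  structure(list(
    gene_id = gene_id, gene_name = gene_name, biotype = biotype,
    chrom = as.character(chrom), strand = as.integer(sign(strand)),
    start = as.integer(min(exons$start)), end = as.integer(max(exons$end)),
    transcripts = list(tx)), class = "gene_model")
}

#' Bundle gene models into an indexed set
#'
#' @param genes list of [gene_model()] objects.
#' @return a `gene_model_set`: the gene list plus a coordinate index used for
#'   interval queries.
#' @export
gene_model_set <- function(genes) {
  idx <- if (length(genes) == 0) {
    data.frame(gene_id = character(0), chrom = character(0),
      start = integer(0), end = integer(0), strand = integer(0))
  } else {
    data.frame(
      gene_id = vapply(genes, `[[`, character(1), "gene_id"),
      chrom = vapply(genes, `[[`, character(1), "chrom"),
      start = as.integer(vapply(genes, function(g) as.numeric(g$start), numeric(1))),
      end = as.integer(vapply(genes, function(g) as.numeric(g$end), numeric(1))),
      strand = as.integer(vapply(genes, function(g) as.numeric(g$strand), numeric(1))),
      stringsAsFactors = FALSE)
  }
  names(genes) <- idx$gene_id
  structure(list(genes = genes, index = idx), class = "gene_model_set")
}

#' Read gene models from GFF3
#'
#' Expects `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` features with `ID`/`Parent` attributes, as written by
#' [write_gff3()] or any conventional GFF3 source. Only the first mRNA per
#' gene is currently modelled per transcript slot; additional mRNAs are kept
#' as further transcripts.
#'
#' @param path GFF3 file.
#' @return a [gene_model_set()].
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  parts <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), , drop = FALSE]
  parts$parent <- vapply(parts$Parent, function(p) p[[1]], character(1))
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    g_mrnas <- mrnas[vapply(mrnas$Parent, function(p) p[[1]], character(1)) == gid, , drop = FALSE]
    txs <- lapply(seq_len(nrow(g_mrnas)), function(j) {
      tid <- g_mrnas$ID[j]
      pick <- function(what) {
        sel <- parts[parts$parent == tid & parts$type == what, , drop = FALSE]
        if (nrow(sel) == 0) return(NULL)
        sel <- sel[order(sel$start), ]
        data.frame(start = sel$start, end = sel$end)
      }
      list(transcript_id = tid, exons = pick("exon"), cds = pick("CDS"),
        utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR"))
    })
    biotype <- if ("biotype" %in% names(genes) && !is.na(genes$biotype[i])) {
      genes$biotype[i]
    } else "protein_coding"
    name <- if ("Name" %in% names(genes) && !is.na(genes$Name[i])) genes$Name[i] else gid
    structure(list(
      gene_id = gid, gene_name = name, biotype = biotype,
      chrom = genes$seqnames[i],
      strand = if (as.character(genes$strand[i]) == "-") -1L else 1L,
      start = genes$start[i], end = genes$end[i],
      transcripts = txs), class = "gene_model")
  })
  gene_model_set(out)
}

# overlap length (bp, end-start convention) of SV [s,e] with intervals df;
# INS records are points: any interval containing the point counts.
.ov_any <- function(s, e, iv, is_ins) {
  if (is.null(iv) || nrow(iv) == 0) return(FALSE)
  if (is_ins) any(s >= iv$start & s <= iv$end)
  else any(pmin(e, iv$end) - pmax(s, iv$start) > 0)
}

.introns <- function(tx) {
  ex <- tx$exons
  if (is.null(ex) || nrow(ex) < 2) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = ex$end[-nrow(ex)] + 1, end = ex$start[-1] - 1)
}

# strand-aware ordinal of genomic interval index i among n
.ordinal <- function(i, n, strand) {
  as.integer(if (strand > 0) i else n - i + 1)
}

# classification of one SV against one gene; returns list(class, string, ...)
.classify_one_gene <- function(s, e, is_ins, gene, flank) {
  best <- NULL
  rank <- c(exon_intron = 1, exon = 2, utr = 3, intron = 4)
  for (tx in gene$transcripts) {
    ex <- tx$exons
    intr <- .introns(tx)
    n_ex <- if (is.null(ex)) 0 else nrow(ex)
    n_in <- nrow(intr)
    hit_ex <- if (n_ex) which(vapply(seq_len(n_ex), function(k)
      .ov_any(s, e, ex[k, , drop = FALSE], is_ins), logical(1))) else integer(0)
    hit_in <- if (n_in) which(vapply(seq_len(n_in), function(k)
      .ov_any(s, e, intr[k, , drop = FALSE], is_ins), logical(1))) else integer(0)
    hit_cds <- .ov_any(s, e, tx$cds, is_ins)
    hit_utr <- .ov_any(s, e, tx$utr5, is_ins) || .ov_any(s, e, tx$utr3, is_ins)
    cls <- if (length(hit_ex) && length(hit_in)) "exon_intron"
      else if (hit_cds) "exon"
      else if (hit_utr) "utr"
      else if (length(hit_ex)) "exon"     # exonic, noncoding transcript
      else if (length(hit_in)) "intron"
      else next
    ords_ex <- sort(vapply(hit_ex, .ordinal, integer(1), n = n_ex, strand = gene$strand))
    ords_in <- sort(vapply(hit_in, .ordinal, integer(1), n = n_in, strand = gene$strand))
    str <- paste(c(
      if (length(ords_ex)) sprintf("EXON=%d/%d", ords_ex[1], n_ex),
      if (length(ords_in)) sprintf("INTRON=%d/%d", ords_in[1], n_in),
      sprintf("STRAND=%d", gene$strand)), collapse = ",")
    cand <- list(class = cls, string = str, splice = length(hit_ex) && length(hit_in))
    if (is.null(best) || rank[[cls]] < rank[[best$class]]) best <- cand
  }
  if (!is.null(best)) return(best)
  # inside the gene span but matching no transcript feature (should not occur)
  if (.ov_any(s, e, data.frame(start = gene$start, end = gene$end), is_ins)) {
    return(list(class = "intron",
      string = sprintf("STRAND=%d", gene$strand), splice = FALSE))
  }
  # flank
  dist <- if (e < gene$start) gene$start - e else s - gene$end
  if (dist <= flank && dist > 0) {
    return(list(class = "upstream_downstream",
      string = sprintf("DISTANCE=%d,STRAND=%d", dist, gene$strand),
      splice = FALSE, distance = dist))
  }
  NULL
}

#' Classify the genomic location of merged SVs against a gene model
#'
#' Each SV receives exactly one location class with precedence
#' `exon_intron` (spans an exon-intron boundary) > `exon` (overlaps coding or
#' exonic sequence only) > `utr` > `intron` > `upstream_downstream` (within
#' `flank` bp of a gene span) > `intergenic`. When an SV overlaps several
#' genes all are listed and the highest-precedence location wins. Exon/intron
#' ordinals are strand-aware and reported in the conventional
#' `EXON=i/n,INTRON=j/m,STRAND=s` grammar (`DISTANCE=d,STRAND=s` for flanking
#' SVs). Insertions are treated as points at their breakpoint.
#'
#' @param svs merged-SV data.frame (columns `id`, `chrom`, `start`, `end`,
#'   `svtype`).
#' @param genes a [gene_model_set()].
#' @param flank upstream/downstream window in bp (default 5000, the
#'   conventional annotator flank; printed candidate tables list distances up
#'   to ~4.4 kb as gene-associated).
#' @return data.frame with columns `sv_id`, `location`, `location_string`,
#'   `genes` (comma-joined gene ids), `gene_names`, `distance` (NA unless
#'   `upstream_downstream`), `splice_boundary` (logical helper for impact
#'   prediction).
#' @export
classify_location <- function(svs, genes, flank = 5000) {
  idx <- genes$index
  known_chroms <- unique(idx$chrom)
  res <- lapply(seq_len(nrow(svs)), function(i) {
    s <- svs$start[i]; e <- svs$end[i]
    is_ins <- svs$svtype[i] == "INS"
    if (!(svs$chrom[i] %in% known_chroms)) {
      warning("chromosome ", svs$chrom[i], " absent from the gene model; ",
        "classifying as intergenic", call. = FALSE)
      cand <- idx[0, ]
    } else {
      near <- idx$chrom == svs$chrom[i] & idx$start - flank <= e & idx$end + flank >= s
      cand <- idx[near, , drop = FALSE]
    }
    rank <- c(exon_intron = 1, exon = 2, utr = 3, intron = 4,
      upstream_downstream = 5, intergenic = 6)
    best <- NULL; hit_genes <- character(0); hit_names <- character(0)
    for (gid in cand$gene_id) {
      r <- .classify_one_gene(s, e, is_ins, genes$genes[[gid]], flank)
      if (is.null(r)) next
      if (r$class != "upstream_downstream") {
        hit_genes <- c(hit_genes, gid)
        hit_names <- c(hit_names, genes$genes[[gid]]$gene_name)
      }
      if (is.null(best) || rank[[r$class]] < rank[[best$class]] ||
          (r$class == "upstream_downstream" && best$class == "upstream_downstream" &&
           r$distance < best$distance)) {
        best <- r
        best$gene <- gid
        best$gene_name <- genes$genes[[gid]]$gene_name
      }
    }
    if (is.null(best)) {
      best <- list(class = "intergenic", string = "", splice = FALSE)
    }
    if (best$class == "upstream_downstream") {
      hit_genes <- best$gene
      hit_names <- best$gene_name
    }
    data.frame(
      sv_id = svs$id[i], location = best$class, location_string = best$string,
      genes = paste(hit_genes, collapse = ","),
      gene_names = paste(hit_names, collapse = ","),
      distance = if (best$class == "upstream_downstream") best$distance else NA_integer_,
      splice_boundary = isTRUE(best$splice),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# stop codon interval: last 3 coding bases along the transcript
.stop_codon <- function(tx, strand) {
  cds <- tx$cds
  if (is.null(cds) || nrow(cds) == 0) return(NULL)
  if (strand > 0) {
    last <- cds[nrow(cds), ]
    data.frame(start = max(last$start, last$end - 2), end = last$end)
  } else {
    first <- cds[1, ]
    data.frame(start = first$start, end = min(first$end, first$start + 2))
  }
}

#' Predict a simplified functional impact for annotated SVs
#'
#' Rules are applied in severity order; the first match fixes the impact
#' class, all applicable consequence terms are retained:
#' 1. DEL/DUP overlapping a transcript's stop codon: `stop_lost`, impact
#'    `high`.
#' 2. DEL/INS/DUP contained in coding sequence whose affected CDS length is
#'    not divisible by 3: `frameshift`, impact `high`.
#' 3. SV spanning an exon-intron boundary or lying within `splice_window` bp
#'    of a splice site: `splice_region`, impact `modifier`.
#' 4. SV within a UTR: `utr_change`, `modifier`.
#' 5. SV in the upstream/downstream flank: `regulatory_region`, `modifier`
#'    (a proxy for promoter / transcription-factor-binding-site loss).
#' 6. Purely intronic: `intron_variant`, `modifier`.
#' 7. Intergenic: `intergenic_variant`, impact `none`.
#'
#' @param svs merged-SV data.frame.
#' @param annotations output of [classify_location()], same row order.
#' @param genes the [gene_model_set()].
#' @param splice_window intronic distance from a splice site still counted as
#'   splice region (default 8 bp, the common annotator convention).
#' @return `annotations` with `impact` and `consequences` columns filled.
#' @export
predict_impact <- function(svs, annotations, genes, splice_window = 8) {
  stopifnot(nrow(svs) == nrow(annotations))
  imp <- character(nrow(svs)); cons <- character(nrow(svs))
  for (i in seq_len(nrow(svs))) {
    s <- svs$start[i]; e <- svs$end[i]
    type <- svs$svtype[i]; is_ins <- type == "INS"
    ann <- annotations[i, ]
    gids <- if (nzchar(ann$genes)) strsplit(ann$genes, ",", fixed = TRUE)[[1]] else character(0)
    found <- character(0)
    for (gid in gids) {
      g <- genes$genes[[gid]]
      for (tx in g$transcripts) {
        stop_iv <- .stop_codon(tx, g$strand)
        if (type %in% c("DEL", "DUP") && !is.null(stop_iv) &&
            .ov_any(s, e, stop_iv, FALSE)) {
          found <- union(found, "stop_lost")
        }
        if (!is.null(tx$cds) && nrow(tx$cds) > 0) {
          cds_ir <- IRanges::IRanges(tx$cds$start, tx$cds$end)
          if (is_ins) {
            inside <- any(s >= tx$cds$start & s <= tx$cds$end)
            if (inside && svs$length[i] %% 3 != 0) found <- union(found, "frameshift")
          } else {
            # span SVs cover bases start+1..end (length == end - start)
            sv_ir <- IRanges::IRanges(s + 1, e)
            ovl <- sum(IRanges::width(IRanges::intersect(sv_ir, cds_ir)))
            contained <- ovl == (e - s)
            if (contained && ovl %% 3 != 0 && type %in% c("DEL", "DUP")) {
              found <- union(found, "frameshift")
            }
          }
        }
        # splice proximity: within splice_window bp into an intron
        intr <- .introns(tx)
        if (nrow(intr) > 0 && !is_ins) {
          near_site <- any(
            (s >= intr$start & s <= intr$start + splice_window - 1) |
            (e >= intr$end - splice_window + 1 & e <= intr$end))
          if (near_site) found <- union(found, "splice_region")
        }
      }
    }
    if (isTRUE(ann$splice_boundary)) found <- union(found, "splice_region")
    if (ann$location == "utr") found <- union(found, "utr_change")
    if (ann$location == "upstream_downstream") found <- union(found, "regulatory_region")
    if (ann$location == "intron" && length(found) == 0) found <- "intron_variant"
    if (ann$location == "intergenic") found <- "intergenic_variant"
    imp[i] <- if (any(found %in% c("stop_lost", "frameshift"))) "high"
      else if (any(found %in% c("splice_region", "utr_change",
        "regulatory_region", "intron_variant"))) "modifier"
      else "none"
    cons[i] <- paste(found, collapse = ",")
  }
  annotations$impact <- imp
  annotations$consequences <- cons
  annotations
}

#' Classify and impact-annotate a merged call set in one step
#'
#' @inheritParams classify_location
#' @inheritParams predict_impact
#' @return annotation data.frame with location and impact columns.
#' @export
annotate_svs <- function(svs, genes, flank = 5000, splice_window = 8) {
  ann <- classify_location(svs, genes, flank = flank)
  predict_impact(svs, ann, genes, splice_window = splice_window)
}

#' Summarise location classes
#'
#' Counts and percentages per location class; percentages are
#' `100 * count / total`, rounded half-up to 2 decimals.
#'
#' @param annotations data.frame with a `location` column.
#' @return data.frame with `location`, `count`, `percent`; counts sum to the
#'   number of annotations.
#' @export
location_summary <- function(annotations) {
  classes <- c("exon", "exon_intron", "intron", "utr",
    "upstream_downstream", "intergenic")
  if (nrow(annotations) == 0) {
    return(data.frame(location = character(0), count = integer(0),
      percent = numeric(0)))
  }
  counts <- vapply(classes, function(cl) sum(annotations$location == cl), integer(1))
  data.frame(location = classes, count = as.integer(counts),
    percent = round_half_up(100 * counts / nrow(annotations), 2),
    row.names = NULL, stringsAsFactors = FALSE)
}
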