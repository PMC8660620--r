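#' Validate a table of structural-variant calls
#'
#' Checks the coordinate conventions used throughout the package:
#' 1-based inclusive positions; for DEL/DUP/INV, `end > start` and
#' `length == end - start`; for INS, `end == start` and `length > 0`
#' (the inserted-sequence length); `support >= 0`; `svtype` one of
#' DEL, DUP, INS, INV; non-empty `chrom`.
#'
#' @param calls data.frame with columns `chrom`, `start`, `end`, `svtype`,
#'   `length`, `support` (plus any others, which are preserved).
#' @param lenient if `TRUE`, invalid rows are dropped (with a message) instead
#'   of raising an error.
#' @return the validated (possibly subset) data.frame; the character vector of
#'   per-row problems is attached as attribute `"errors"` when `lenient`.
#' @export
validate_sv_calls <- function(calls, lenient = FALSE) {
  required <- c("chrom", "start", "end", "svtype", "length", "support")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(calls) == 0) return(calls)
  probs <- character(0)
  bad <- logical(nrow(calls))
  flag <- function(idx, msg) {
    idx[is.na(idx)] <- TRUE
    if (any(idx)) {
      bad[idx] <<- TRUE
      probs <<- c(probs, sprintf("row %d: %s", which(idx), msg))
    }
  }
  flag(!(calls$svtype %in% SV_TYPES), "svtype not one of DEL/DUP/INS/INV")
  flag(is.na(calls$chrom) | !nzchar(as.character(calls$chrom)), "empty chrom")
  flag(is.na(calls$start) | is.na(calls$end) | calls$start < 1, "bad coordinates")
  flag(is.na(calls$support) | calls$support < 0, "negative support")
  ins <- !is.na(calls$svtype) & calls$svtype == "INS"
  span <- !is.na(calls$svtype) & calls$svtype %in% c("DEL", "DUP", "INV")
  flag(span & !(calls$end > calls$start), "end must exceed start for DEL/DUP/INV")
  flag(span & calls$end > calls$start & calls$length != calls$end - calls$start,
    "length != end - start for DEL/DUP/INV")
  flag(ins & calls$end != calls$start, "end must equal start for INS")
  flag(ins & calls$length <= 0, "INS length must be positive")
  if (any(bad)) {
    if (!lenient) {
      stop("invalid SV calls:\n", paste(probs, collapse = "\n"))
    }
    message(sum(bad), " invalid call(s) dropped")
    calls <- calls[!bad, , drop = FALSE]
    rownames(calls) <- NULL
  }
  attr(calls, "errors") <- probs
  calls
}

#' Read one caller's calls for one individual
#'
#' Reads the normalized caller table: a UTF-8, tab-separated file with a
#' header line and columns `chrom`, `start`, `end`, `svtype`, `length`,
#' `support`. Records on chromosome Y are retained here; dropping them is an
#' explicit later filtering stage (see [apply_cohort_filters()]).
#'
#' @param path path to the TSV file.
#' @param caller_id,sample_id identifiers stamped onto every record.
#' @param lenient passed to [validate_sv_calls()].
#' @return data.frame of validated calls with `caller_id` and `sample_id`
#'   columns prepended.
#' @export
read_caller_calls <- function(path, caller_id, sample_id, lenient = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  calls <- read.delim(path, header = TRUE, sep = "\t",
    colClasses = c(chrom = "character"), stringsAsFactors = FALSE)
  calls <- validate_sv_calls(calls, lenient = lenient)
  if (nrow(calls) > 0) {
    calls <- cbind(caller_id = caller_id, sample_id = sample_id, calls,
      stringsAsFactors = FALSE)
  } else {
    calls <- cbind(calls[0, ], caller_id = character(0), sample_id = character(0))
  }
  rownames(calls) <- NULL
  calls
}

#' Length of a structural variant
#'
#' `end - start` for DEL/DUP/INV (1-based inclusive breakpoint convention in
#' which the printed Length column equals the coordinate difference); the
#' stored inserted-sequence length for INS.
#'
#' @param calls validated call data.frame (any table with `start`, `end`,
#'   `svtype`, `length`).
#' @return integer vector of lengths in bp.
#' @export
sv_length <- function(calls) {
  ifelse(calls$svtype == "INS", calls$length, calls$end - calls$start)
}

#' Write / read the cohort call-set table
#'
#' The cohort table is tab-separated with columns `id`, `chrom`, `start`,
#' `end`, `svtype`, `length`, `n_carriers`, `carriers` (comma-joined sample
#' IDs), sorted by (chrom, start) with IDs `sv_%05d` assigned in that order.
#' `read_cohort_table()` round-trips the table losslessly.
#'
#' @param svs merged-SV data.frame as produced by [merge_cohort()].
#' @param path output path.
#' @return `write_cohort_table()` returns the written data.frame invisibly;
#'   `read_cohort_table()` returns the table.
#' @export
write_cohort_table <- function(svs, path) {
  if (is.null(svs) || nrow(svs) == 0) stop("refusing to write an empty cohort table")
  svs <- svs[chrom_order(svs$chrom), , drop = FALSE]
  svs <- svs[order(match(svs$chrom, unique(svs$chrom)), svs$start, svs$end), , drop = FALSE]
  out <- data.frame(
    id = sprintf("sv_%05d", seq_len(nrow(svs))),
    chrom = svs$chrom, start = svs$start, end = svs$end,
    svtype = svs$svtype, length = svs$length,
    n_carriers = svs$n_carriers, carriers = svs$carriers,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.delim(path, header = TRUE, sep = "\t",
    colClasses = c(chrom = "character", carriers = "character"),
    stringsAsFactors = FALSE)
}

#' Export the cohort call set as a minimal VCF 4.2
#'
#' Symbolic ALT alleles (`<DEL>`, `<DUP>`, `<INS>`, `<INV>`), INFO keys
#' `SVTYPE`, `END` and `SVLEN`, and one genotype column per sample carrying
#' `1` (carrier) or `0` (non-carrier) under the presence/absence model.
#' `POS` is the SV start; for INS, `END == POS` and `SVLEN` is the insert
#' length; SVLEN is negative for deletions.
#'
#' @param svs cohort table (with `id` column, as written by
#'   [write_cohort_table()]).
#' @param sample_ids all cohort samples, in column order.
#' @param path output path.
#' @export
export_vcf <- function(svs, sample_ids, path) {
  carriers <- strsplit(svs$carriers, ",", fixed = TRUE)
  unknown <- setdiff(unlist(carriers), sample_ids)
  if (length(unknown) > 0) {
    stop("carrier sample(s) absent from sample_ids: ", paste(unknown, collapse = ", "))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svcohort",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Difference in length between REF and ALT alleles">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Presence/absence pseudo-genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sample_ids), collapse = "\t"))
  svlen <- ifelse(svs$svtype == "DEL", -svs$length, svs$length)
  gt <- vapply(carriers, function(cs) {
    paste(ifelse(sample_ids %in% cs, "1", "0"), collapse = "\t")
  }, character(1))
  body <- paste(svs$chrom, svs$start, svs$id, "N",
    paste0("<", svs$svtype, ">"), ".", "PASS",
    sprintf("SVTYPE=%s;END=%d;SVLEN=%d", svs$svtype, svs$end, svlen),
    "GT", gt, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated, header line, columns `sample_id` and `group`.
#'
#' @param path path to the sample sheet.
#' @return data.frame with `sample_id` and `group`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    stop("sample sheet needs columns sample_id and group")
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample_id in sample sheet")
  sheet
}

#' Read / write gene sets in GMT format
#'
#' One term per line: term id, description, then member gene ids, all
#' tab-separated. The description field carries free-text tags (e.g.
#' `skin_aging`) used by [screen_candidates()] to recognise relevant terms.
#'
#' @param path GMT file path.
#' @param gene_sets list of lists with `term_id`, `term_name`, `genes`.
#' @return `read_gmt()`: a list of such lists.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", ln)
    list(term_id = parts[1], term_name = parts[2], genes = unique(parts[-(1:2)]))
  })
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(gene_sets, function(gs) {
    paste(c(gs$term_id, gs$term_name, gs$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain gene list (one gene id per line)
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  genes <- readLines(path)
  unique(genes[nzchar(genes)])
}
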