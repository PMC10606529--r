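#' Parse a RepeatMasker `.out` annotation table
#'
#' Reads the standard whitespace-delimited `.out` layout (15 data columns
#' plus an optional trailing `*` marking lower-scoring overlaps). The 3-line
#' header and blank lines are skipped; headerless files are accepted. No
#' filtering is applied here: every data row becomes one hit, whatever its
#' repeat class.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A data.frame with one row per hit: `sw_score`, `pct_div`,
#'   `pct_del`, `pct_ins`, `query_id`, `query_start`, `query_end` (1-based
#'   inclusive query coordinates), `orientation` (`+` or `C`), `repeat_name`,
#'   `repeat_class_family`.
#' @export
read_rm_out <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  # header lines start with the column-label words, not a numeric score
  is_header <- grepl("^\\s*(SW|score|bit)", lines)
  keep <- keep & !is_header
  lines <- lines[keep]
  ln <- ln[keep]
  empty <- data.frame(
    sw_score = integer(0), pct_div = numeric(0), pct_del = numeric(0),
    pct_ins = numeric(0), query_id = character(0), query_start = integer(0),
    query_end = integer(0), orientation = character(0),
    repeat_name = character(0), repeat_class_family = character(0),
    stringsAsFactors = FALSE
  )
  if (length(lines) == 0L) {
    return(empty)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("RepeatMasker .out parse error at line ", ln[which(nf < 11L)[1L]],
         ": expected >= 11 whitespace-delimited columns")
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(x, what, integer = FALSE) {
    v <- suppressWarnings(if (integer) as.integer(x) else as.numeric(x))
    if (anyNA(v)) {
      stop("RepeatMasker .out parse error at line ", ln[which(is.na(v))[1L]],
           ": non-numeric ", what)
    }
    v
  }
  out <- data.frame(
    sw_score = num(col(1), "score", integer = TRUE),
    pct_div = num(col(2), "divergence"),
    pct_del = num(col(3), "deletion percentage"),
    pct_ins = num(col(4), "insertion percentage"),
    query_id = col(5),
    query_start = num(col(6), "query start", integer = TRUE),
    query_end = num(col(7), "query end", integer = TRUE),
    orientation = col(9),
    repeat_name = col(10),
    repeat_class_family = col(11),
    stringsAsFactors = FALSE
  )
  bad <- out$query_start > out$query_end
  if (any(bad)) {
    stop("RepeatMasker .out parse error at line ", ln[which(bad)[1L]],
         ": query_start > query_end")
  }
  out
}

#' Select reads by L1 divergence
#'
#' A read qualifies when any of its hits is of the given repeat class (prefix
#' match, so subfamily-annotated variants such as `LINE/L1/L1HS` also match)
#' and is less than `max_div` percent diverged from the consensus (strict
#' inequality: a hit at exactly `max_div` does not qualify).
#'
#' @param hits data.frame from [read_rm_out()].
#' @param max_div Maximum percent divergence (exclusive). Default 10.
#' @param class_prefix Repeat class/family prefix to match. Default
#'   `"LINE/L1"`.
#' @return Character vector of unique qualifying read identifiers, in first
#'   appearance order.
#' @export
select_reads_by_divergence <- function(hits, max_div = 10,
                                       class_prefix = "LINE/L1") {
  stopifnot(is.data.frame(hits), max_div > 0, max_div <= 100)
  ok <- startsWith(hits$repeat_class_family, class_prefix) &
    hits$pct_div < max_div
  unique(hits$query_id[ok])
}

#' Write the subset of reads with qualifying L1 hits
#'
#' Convenience wrapper combining [read_rm_out()],
#' [select_reads_by_divergence()] and FASTA/FASTQ subsetting.
#'
#' @param reads A `DNAStringSet`/`QualityScaledDNAStringSet` or path to a
#'   FASTA/FASTQ file.
#' @param rm_out Path to the matching RepeatMasker `.out` file.
#' @param out Optional FASTA output path.
#' @inheritParams select_reads_by_divergence
#' @return The selected reads as a `DNAStringSet` (invisibly when `out` is
#'   written).
#' @export
select_l1_reads <- function(reads, rm_out, out = NULL, max_div = 10,
                            class_prefix = "LINE/L1") {
  if (is.character(reads)) {
    fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  names(reads) <- sub("\\s.*$", "", names(reads))
  ids <- select_reads_by_divergence(read_rm_out(rm_out),
                                    max_div = max_div,
                                    class_prefix = class_prefix)
  sel <- reads[names(reads) %in% ids]
  if (!is.null(out)) {
    Biostrings::writeXStringSet(sel, out)
    return(invisible(sel))
  }
  sel
}
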