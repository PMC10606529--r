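#' Read a BED file into a GRanges
#'
#' Parses BED3/BED6 (tab-separated, 0-based half-open coordinates) into a
#' `GRanges` (1-based, closed, the native R container). Column 4 (name) and
#' column 6 (strand) are honored when present; row order is preserved.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges] with an mcols column `name` (empty
#'   string where absent).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tUID-1\t0\t+", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(name = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", which(nf < 3L)[1L], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s_chr <- vapply(fields, `[[`, character(1), 2L)
  e_chr <- vapply(fields, `[[`, character(1), 3L)
  start0 <- suppressWarnings(as.integer(s_chr))
  end0 <- suppressWarnings(as.integer(e_chr))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad)) {
    stop("BED parse error at line ", which(bad)[1L], ": non-integer coordinates")
  }
  bad <- start0 < 0L | start0 >= end0
  if (any(bad)) {
    stop("BED parse error at line ", which(bad)[1L],
         ": requires 0 <= start < end")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))],
                                  character(1)), "")
  name[nf < 4L] <- ""
  strand <- rep("*", length(fields))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, character(1), 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand,
    name = name
  )
}

#' Write a GRanges as BED6
#'
#' Inverse of [read_bed()]: writes 0-based half-open coordinates, name from
#' the mcols column `name` (or `uid` if present), score 0, strand (`.` for
#' `*`).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  name <- if (!is.null(gr$uid)) gr$uid else if (!is.null(gr$name)) gr$name else "."
  name[is.na(name) | !nzchar(name)] <- "."
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = name,
    score = 0L,
    strand = strand
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load exon intervals from a GTF or BED file
#'
#' For GTF input (GENCODE dialect; extensions `.gtf` / `.gtf.gz`) all rows of
#' feature type `"exon"` across all transcripts are used, unmerged. Anything
#' else is read as BED.
#'
#' @param path Path to a GTF or BED file.
#' @return A `GRanges` of exon intervals.
#' @export
read_exons <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    gtf <- rtracklayer::import(path, format = "gtf")
    exons <- gtf[!is.na(gtf$type) & gtf$type == "exon"]
    S4Vectors::mcols(exons) <- NULL
    exons$name <- ""
    exons
  } else {
    read_bed(path)
  }
}

#' Remove intervals that overlap a blocking set
#'
#' Drops, whole, every `primary` interval sharing at least one base with any
#' `blocking` interval (`bedtools intersect -v` semantics). Overlap is
#' strand-blind; abutting half-open intervals do not overlap. Intervals are
#' never clipped.
#'
#' @param primary,blocking `GRanges` objects in the same coordinate system.
#' @return The subset of `primary` with zero overlap, original order kept.
#' @export
subtract_overlapping <- function(primary, blocking) {
  stopifnot(is(primary, "GRanges"), is(blocking, "GRanges"))
  if (length(blocking) == 0L || length(primary) == 0L) {
    return(primary)
  }
  hit <- IRanges::overlapsAny(primary, blocking, ignore.strand = TRUE)
  primary[!hit]
}

#' Exclude L1 regions that overlap exons
#'
#' Identical semantics to [subtract_overlapping()] (strand-blind,
#' whole-interval removal); kept as a named step because exon exclusion is a
#' distinct stage of reference preparation.
#'
#' @param regions `GRanges` of L1 regions.
#' @param exons `GRanges` of exon intervals (may be empty).
#' @return Surviving regions, metadata untouched.
#' @export
exclude_exon_overlaps <- function(regions, exons) {
  subtract_overlapping(regions, exons)
}
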