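#' Read primary genome alignments
#'
#' Parses a SAM or BAM file (SAM is converted on the fly) and yields only
#' mapped, primary, non-supplementary records — secondary and supplementary
#' placements never enter the analysis.
#'
#' @param path Path to a SAM or BAM file.
#' @return A [GenomicAlignments::GAlignments], named by read id, with a
#'   `mapq` mcols column.
#' @export
read_primary_alignments <- function(path) {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE
    ),
    what = "mapq"
  )
  GenomicAlignments::readGAlignments(bam, use.names = TRUE, param = param)
}

#' Reference span and reference-consuming blocks of alignments
#'
#' The span runs from the alignment start to its rightmost reference base
#' (inclusive of deletions and N skips). Blocks are maximal runs of
#' reference-consuming CIGAR operations (`M`, `=`, `X`, `D`), split only at
#' `N` (introns); soft/hard clips and insertions consume no reference.
#'
#' @param aln A `GAlignments`.
#' @return A list with `span` (a `GRanges`, one range per alignment) and
#'   `blocks` (a `GRangesList`, split at N, parallel to `span`).
#' @export
alignment_blocks <- function(aln) {
  span <- GenomicRanges::granges(aln, use.names = TRUE, use.mcols = FALSE)
  blocks <- GenomicAlignments::grglist(aln, drop.D.ranges = FALSE)
  list(span = span, blocks = blocks)
}

#' Fraction of each alignment span contained in the L1 regions
#'
#' For each alignment, the number of bases of its reference span that fall
#' inside the union of the regions, divided by the span length. Computing
#' against the union means a read bridging two adjacent L1 records is not
#' penalized, and the value is invariant under splitting a region into
#' adjacent pieces.
#'
#' @param aln A `GAlignments`.
#' @param regions A `GRanges` of L1 regions.
#' @param use_blocks If `TRUE`, the numerator and denominator are computed
#'   over the reference-consuming blocks (split at N) instead of the full
#'   span. Default `FALSE`, matching span semantics.
#' @return Numeric vector in `[0, 1]`, parallel to `aln`.
#' @export
containment_fraction <- function(aln, regions, use_blocks = FALSE) {
  stopifnot(is(regions, "GRanges"))
  geom <- alignment_blocks(aln)
  target <- if (use_blocks) unlist(geom$blocks) else geom$span
  idx <- if (use_blocks) rep(seq_along(aln), lengths(geom$blocks))
         else seq_along(aln)
  denom <- as.numeric(tapply(BiocGenerics::width(target), idx, sum))
  if (any(denom == 0)) {
    stop("zero-length alignment span")
  }
  red <- GenomicRanges::reduce(GenomicRanges::granges(regions),
                               ignore.strand = TRUE)
  ov <- rep(0, length(aln))
  if (length(red) > 0L && length(target) > 0L) {
    hits <- GenomicRanges::findOverlaps(target, red, ignore.strand = TRUE)
    if (length(hits) > 0L) {
      w <- BiocGenerics::width(IRanges::pintersect(
        GenomicRanges::ranges(target)[S4Vectors::queryHits(hits)],
        GenomicRanges::ranges(red)[S4Vectors::subjectHits(hits)]
      ))
      agg <- tapply(w, idx[S4Vectors::queryHits(hits)], sum)
      ov[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  ov / denom
}

.assign_locus <- function(aln, regions) {
  # region with largest span overlap; ties to the leftmost region
  span <- GenomicRanges::granges(aln, use.mcols = FALSE)
  hits <- GenomicRanges::findOverlaps(span, regions, ignore.strand = TRUE)
  out <- rep(NA_integer_, length(aln))
  if (length(hits) == 0L) {
    return(out)
  }
  w <- BiocGenerics::width(IRanges::pintersect(
    GenomicRanges::ranges(span)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(regions)[S4Vectors::subjectHits(hits)]
  ))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ord <- order(q, -w, BiocGenerics::start(regions)[s], s)
  first <- !duplicated(q[ord])
  out[q[ord][first]] <- s[ord][first]
  out
}

#' Containment filter with locus assignment
#'
#' Keeps alignments whose span is contained in the region union at a fraction
#' of at least `min_frac` ("at least 90% of the read mapped within the L1
#' regions"), and assigns each kept alignment to the single region with the
#' largest span overlap (ties to the leftmost region).
#'
#' @inheritParams containment_fraction
#' @param min_frac Minimum containment fraction, inclusive. Default 0.9.
#' @return A `GAlignments` subset of `aln` with added mcols `locus_uid`,
#'   `locus_category` and `containment`.
#' @export
filter_by_containment <- function(aln, regions, min_frac = 0.9,
                                  use_blocks = FALSE) {
  if (length(regions) == 0L || length(aln) == 0L) {
    return(aln[rep(FALSE, length(aln))])
  }
  frac <- containment_fraction(aln, regions, use_blocks = use_blocks)
  kept <- aln[frac >= min_frac]
  idx <- .assign_locus(kept, regions)
  S4Vectors::mcols(kept)$locus_uid <- regions$uid[idx]
  S4Vectors::mcols(kept)$locus_category <-
    if (!is.null(regions$category)) regions$category[idx] else NA_character_
  S4Vectors::mcols(kept)$containment <- frac[frac >= min_frac]
  kept
}

#' Read-to-locus assignment table
#'
#' Flattens the output of [filter_by_containment()] into the TSV contract
#' consumed by the locus filter: one row per kept read with its locus UID and
#' 0-based alignment start.
#'
#' @param aln A `GAlignments` from [filter_by_containment()].
#' @param path Optional TSV output path.
#' @return A data.frame: `read_id`, `uid`, `category`, `start0`.
#' @export
read_locus_table <- function(aln, path = NULL) {
  df <- data.frame(
    read_id = if (is.null(names(aln))) rep(NA_character_, length(aln))
              else names(aln),
    uid = S4Vectors::mcols(aln)$locus_uid,
    category = S4Vectors::mcols(aln)$locus_category,
    start0 = BiocGenerics::start(aln) - 1L,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
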