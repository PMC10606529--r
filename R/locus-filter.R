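#' Most common read start position
#'
#' Ties are broken toward the smaller coordinate so the result is
#' deterministic.
#'
#' @param starts Non-empty numeric vector of alignment start positions.
#' @return The modal start.
#' @export
modal_start <- function(starts) {
  if (length(starts) == 0L) {
    stop("modal_start requires a non-empty vector")
  }
  tab <- table(starts)
  as.numeric(names(tab)[tab == max(tab)][1L])
}

#' Artifact-based locus filters
#'
#' Judges each reference L1 locus on its containment-passing primary reads,
#' in this order:
#' \enumerate{
#'   \item fewer than `min_reads` mapped reads — `too_few_reads`;
#'   \item any read start more than `start_window` bases from the most common
#'     start — `inconsistent_starts` (with `trim_outliers = TRUE` the
#'     deviating reads are dropped instead and the remaining set is
#'     re-judged);
#'   \item modal start more than `max_start_offset` bases from the reference
#'     L1 start position — `start_too_far`;
#'   \item otherwise `ok`.
#' }
#' Verdicts are per-locus independent. All thresholds are inclusive on the
#' keep side: a deviation of exactly `start_window`, or an offset of exactly
#' `max_start_offset`, is kept. By default the "reference L1 start position"
#' is the lower genomic coordinate (BED start) regardless of strand;
#' `strand_aware = TRUE` uses the biological 5' end (BED end for minus-strand
#' regions).
#'
#' @param assign Read-to-locus table from [read_locus_table()] (columns
#'   `read_id`, `uid`, `start0`).
#' @param regions An [l1_regions()] `GRanges`; every region receives a
#'   verdict, also those with zero assigned reads.
#' @param min_reads Minimum mapped reads per locus, default 2.
#' @param start_window Maximum deviation (bases) from the modal start,
#'   default 100.
#' @param max_start_offset Maximum distance (bases) of the modal start from
#'   the reference start, default 1500 (reads starting near the L1 5' end are
#'   taken as evidence of autonomous transcription).
#' @param strand_aware Use the biological 5' end as reference point.
#' @param trim_outliers Drop start-deviating reads instead of removing the
#'   locus.
#' @return A list: `verdicts` (data.frame `uid`, `category`, `n_reads`,
#'   `modal_start`, `kept`, `reason`) and `reads` (the rows of `assign` at
#'   kept loci, unchanged; loci with any failure contribute no reads).
#' @export
apply_locus_filters <- function(assign, regions, min_reads = 2L,
                                start_window = 100L,
                                max_start_offset = 1500L,
                                strand_aware = FALSE,
                                trim_outliers = FALSE) {
  stopifnot(is.data.frame(assign), is(regions, "GRanges"))
  ref_start0 <- BiocGenerics::start(regions) - 1L
  if (strand_aware) {
    minus <- as.character(BiocGenerics::strand(regions)) == "-"
    ref_start0[minus] <- BiocGenerics::end(regions)[minus]
  }
  verdicts <- data.frame(
    uid = regions$uid,
    category = regions$category,
    n_reads = 0L,
    modal_start = NA_real_,
    kept = FALSE,
    reason = "too_few_reads",
    stringsAsFactors = FALSE
  )
  kept_rows <- assign[0, , drop = FALSE]
  for (i in seq_along(regions)) {
    rows <- assign[!is.na(assign$uid) & assign$uid == regions$uid[i], ,
                   drop = FALSE]
    starts <- rows$start0
    if (length(starts) > 0L) {
      m <- modal_start(starts)
      if (trim_outliers) {
        ok <- abs(starts - m) <= start_window
        rows <- rows[ok, , drop = FALSE]
        starts <- starts[ok]
        if (length(starts) > 0L) m <- modal_start(starts)
      }
      verdicts$n_reads[i] <- length(starts)
      verdicts$modal_start[i] <- if (length(starts) > 0L) m else NA_real_
    }
    if (verdicts$n_reads[i] < min_reads) {
      verdicts$reason[i] <- "too_few_reads"
    } else if (!trim_outliers &&
               any(abs(starts - verdicts$modal_start[i]) > start_window)) {
      verdicts$reason[i] <- "inconsistent_starts"
    } else if (abs(verdicts$modal_start[i] - ref_start0[i]) >
               max_start_offset) {
      verdicts$reason[i] <- "start_too_far"
    } else {
      verdicts$reason[i] <- "ok"
      verdicts$kept[i] <- TRUE
      kept_rows <- rbind(kept_rows, rows)
    }
  }
  list(verdicts = verdicts, reads = kept_rows)
}
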