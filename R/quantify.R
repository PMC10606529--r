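#' Split-aware genome coverage (bedGraph model)
#'
#' Depth at a base is the number of aligned segments covering it: CIGAR `N`
#' skips and deletions (`D`) contribute nothing, the split-aware coverage
#' convention for spliced long reads. The track tiles every declared sequence
#' completely, zero-depth intervals included, with maximal runs of constant
#' depth (adjacent intervals always differ in depth).
#'
#' @param aln A `GAlignments` (e.g. from [read_primary_alignments()]).
#' @param seqlengths Named integer vector declaring sequence lengths; default
#'   taken from the alignment header.
#' @return A data.frame bedGraph track: `chrom`, `start0` (0-based), `end`,
#'   `depth`.
#' @export
genome_coverage <- function(aln, seqlengths = GenomeInfoDb::seqlengths(aln)) {
  if (anyNA(seqlengths)) {
    stop("all declared sequences need a length")
  }
  blocks <- unlist(GenomicAlignments::grglist(aln, drop.D.ranges = TRUE),
                   use.names = FALSE)
  if (length(blocks) > 0L &&
      any(BiocGenerics::end(blocks) >
          seqlengths[as.character(GenomicRanges::seqnames(blocks))])) {
    stop("alignment extends beyond the declared sequence length")
  }
  out <- lapply(names(seqlengths), function(sq) {
    ir <- GenomicRanges::ranges(
      blocks[GenomicRanges::seqnames(blocks) == sq]
    )
    rle <- IRanges::coverage(ir, width = seqlengths[[sq]])
    ends <- cumsum(S4Vectors::runLength(rle))
    data.frame(
      chrom = sq,
      start0 = c(0L, head(ends, -1L)),
      end = ends,
      depth = S4Vectors::runValue(rle),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Write a coverage track as a 4-column bedGraph
#'
#' @param track data.frame from [genome_coverage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mean coverage of L1 regions
#'
#' `interval_mean` (the default) is the unweighted arithmetic mean of the
#' depth values of the track intervals overlapping the region — the semantics
#' of mapping a bedGraph's value column onto regions with a mean aggregator.
#' `base_mean` is the per-base average depth over the region. The two differ
#' whenever overlapping intervals have unequal widths. A region overlapping
#' no interval scores 0.
#'
#' @param track data.frame from [genome_coverage()].
#' @param regions A `GRanges`.
#' @param mode `"interval_mean"` or `"base_mean"`.
#' @return Numeric vector of means, parallel to `regions`.
#' @export
mean_coverage <- function(track, regions,
                          mode = c("interval_mean", "base_mean")) {
  mode <- match.arg(mode)
  stopifnot(is(regions, "GRanges"))
  absent <- setdiff(as.character(GenomicRanges::seqnames(regions)),
                    unique(track$chrom))
  if (length(absent) > 0L) {
    stop("region sequence absent from coverage track: ",
         paste(absent, collapse = ", "))
  }
  vapply(seq_along(regions), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(regions))[i]
    rs0 <- BiocGenerics::start(regions)[i] - 1L
    re <- BiocGenerics::end(regions)[i]
    t <- track[track$chrom == chrom & track$start0 < re & track$end > rs0, ,
               drop = FALSE]
    if (nrow(t) == 0L) {
      return(0)
    }
    if (mode == "interval_mean") {
      mean(t$depth)
    } else {
      w <- pmin(t$end, re) - pmax(t$start0, rs0)
      sum(t$depth * w) / (re - rs0)
    }
  }, numeric(1))
}

#' Library-size normalization
#'
#' Scales a per-locus mean coverage by the total number of reads in the
#' sample, in millions: `mean_cov / total_reads * scale`.
#'
#' @param mean_cov Numeric vector of per-locus mean coverages.
#' @param total_reads Total reads in the sample (> 0).
#' @param scale Scaling constant, default `1e6`.
#' @return Normalized values.
#' @export
normalize_expression <- function(mean_cov, total_reads, scale = 1e6) {
  if (length(total_reads) != 1L || is.na(total_reads) || total_reads <= 0) {
    stop("total_reads must be a single positive count")
  }
  mean_cov / total_reads * scale
}

#' Length-weighted category average expression
#'
#' The category-level expression value
#' \deqn{\frac{\sum_{r} v_r \cdot L_r}{\sum_{r} L_r}}
#' over the loci of one category, where \eqn{v_r} is the normalized per-locus
#' value and \eqn{L_r} the reference element length. All reference loci of
#' the category belong in the sum — loci removed by the artifact filters
#' contribute value 0 but keep their length in the denominator (use
#' `expressed_only = TRUE` to restrict to surviving loci).
#'
#' @param lengths Element lengths in bases (> 0).
#' @param values Normalized per-locus values, parallel to `lengths`.
#' @param expressed_only Restrict to loci with value > 0.
#' @return The weighted average (a single number).
#' @examples
#' weighted_average(c(6000, 4000), c(2.0, 0.5)) # 1.4
#' @export
weighted_average <- function(lengths, values, expressed_only = FALSE) {
  stopifnot(length(lengths) == length(values))
  if (expressed_only) {
    keep <- values > 0
    lengths <- lengths[keep]
    values <- values[keep]
  }
  if (length(lengths) == 0L) {
    stop("weighted_average over an empty locus list")
  }
  stopifnot(all(lengths > 0))
  sum(values * lengths) / sum(lengths)
}

#' Per-locus quantification
#'
#' Combines [genome_coverage()], [mean_coverage()] and
#' [normalize_expression()] into the per-locus expression table. Loci not in
#' `kept_uids` (removed by artifact filters) are reported with zero coverage.
#'
#' @param aln `GAlignments` of reads surviving all filters.
#' @param regions An [l1_regions()] `GRanges` (all reference loci of the
#'   categories of interest).
#' @param total_reads Sample read total used for normalization.
#' @param kept_uids UIDs of loci that survived the locus filters; `NULL`
#'   means all.
#' @param mode Mean mode, see [mean_coverage()].
#' @param seqlengths Declared sequence lengths for the coverage track.
#' @param scale Normalization scale, default `1e6`.
#' @return A list: `track` (bedGraph data.frame) and `loci` (data.frame
#'   `uid`, `category`, `subfamily`, `length`, `mean_cov`, `normalized`).
#' @export
quantify_loci <- function(aln, regions, total_reads, kept_uids = NULL,
                          mode = "interval_mean",
                          seqlengths = GenomeInfoDb::seqlengths(aln),
                          scale = 1e6) {
  track <- genome_coverage(aln, seqlengths = seqlengths)
  mc <- mean_coverage(track, regions, mode = mode)
  if (!is.null(kept_uids)) {
    mc[!(regions$uid %in% kept_uids)] <- 0
  }
  loci <- data.frame(
    uid = regions$uid,
    category = regions$category,
    subfamily = regions$subfamily,
    length = BiocGenerics::width(regions),
    mean_cov = mc,
    normalized = normalize_expression(mc, total_reads, scale = scale),
    stringsAsFactors = FALSE
  )
  list(track = track, loci = loci)
}

#' Per-category summary
#'
#' Length-weighted average expression and expressed-locus count for each L1
#' category present in the locus table.
#'
#' @param loci Locus table from [quantify_loci()].
#' @param expressed_only Passed to [weighted_average()].
#' @return data.frame: `category`, `n_loci`, `n_expressed`,
#'   `weighted_average`.
#' @export
category_summary <- function(loci, expressed_only = FALSE) {
  cats <- intersect(L1_CATEGORIES, unique(loci$category))
  do.call(rbind, lapply(cats, function(cat) {
    sub <- loci[loci$category == cat, , drop = FALSE]
    wa <- if (expressed_only && !any(sub$normalized > 0)) 0
          else weighted_average(sub$length, sub$normalized,
                                expressed_only = expressed_only)
    data.frame(
      category = cat,
      n_loci = nrow(sub),
      n_expressed = sum(sub$normalized > 0),
      weighted_average = wa,
      stringsAsFactors = FALSE
    )
  }))
}

#' Subfamily breakdown of expressed active loci
#'
#' Counts expressed loci (normalized value > 0) of one category per L1
#' subfamily. The young subfamilies L1HS and L1PA2 are reported individually;
#' anything else, including loci without a subfamily annotation, is pooled
#' under `other`. Percentages are over all expressed loci of the category
#' (0 when none are expressed).
#'
#' @param loci Locus table from [quantify_loci()].
#' @param category Category to summarize, default `"active"`.
#' @param subfamilies Subfamilies to report individually.
#' @return data.frame: `subfamily`, `n_expressed`, `pct`.
#' @export
subfamily_report <- function(loci, category = "active",
                             subfamilies = c("L1HS", "L1PA2")) {
  sub <- loci[loci$category == category & loci$normalized > 0, , drop = FALSE]
  fam <- ifelse(is.na(sub$subfamily) | !(sub$subfamily %in% subfamilies),
                "other", sub$subfamily)
  lv <- c(subfamilies, "other")
  counts <- table(factor(fam, levels = lv))
  total <- sum(counts)
  data.frame(
    subfamily = lv,
    n_expressed = as.integer(counts),
    pct = if (total > 0) as.numeric(counts) / total * 100 else rep(0, length(lv)),
    stringsAsFactors = FALSE
  )
}
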