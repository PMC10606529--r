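#' Run the full L1 expression pipeline
#'
#' Executes the stages in order: read QC (quality and length filter),
#' divergence-based candidate selection from RepeatMasker output, reference
#' pruning (inactive-overlap removal for active elements, exon exclusion for
#' all categories), primary-alignment parsing, containment filtering with
#' locus assignment, artifact-based locus filters, split-aware coverage and
#' length-weighted normalized quantification, plus the subfamily breakdown of
#' expressed active loci.
#'
#' @param fastq Path to the sample reads (FASTQ or FASTA).
#' @param rm_out Path to the RepeatMasker `.out` annotation of the reads.
#' @param sam Path to splice-aware genome alignments (SAM or BAM).
#' @param active_bed,inactive_bed,orf2_bed Paths to the three L1 category
#'   BEDs.
#' @param exons Path to the exon annotation (GTF or BED), or `NULL`.
#' @param rmsk_track Optional path to a RepeatMasker genome-track TSV used to
#'   annotate active-locus subfamilies.
#' @param out_dir Optional output directory for all intermediates and
#'   summaries.
#' @param min_q,min_len Read QC thresholds (defaults 7 and 1000).
#' @param max_div Divergence threshold in percent, exclusive (default 10).
#' @param min_frac Containment threshold, inclusive (default 0.9).
#' @param min_reads,start_window,max_start_offset Locus filter thresholds
#'   (defaults 2, 100, 1500), see [apply_locus_filters()].
#' @param mean_mode `"interval_mean"` or `"base_mean"`, see
#'   [mean_coverage()].
#' @param total_reads Normalization total; default is the number of reads
#'   passing the quality filter (the earliest per-sample total the pipeline
#'   sees), see [qc_reads()].
#' @param scale Normalization scale (default `1e6`).
#' @param expressed_only,strand_aware,trim_outliers Mode flags, see
#'   [weighted_average()] and [apply_locus_filters()].
#' @return A list: `stats` (per-stage read/locus counts), `refs` (pruned
#'   references), `verdicts`, `kept_reads`, `track`, `loci`, `summary`,
#'   `subfamily`, `total_reads`.
#' @export
run_l1_pipeline <- function(fastq, rm_out, sam,
                            active_bed, inactive_bed, orf2_bed,
                            exons = NULL, rmsk_track = NULL, out_dir = NULL,
                            min_q = 7, min_len = 1000L, max_div = 10,
                            min_frac = 0.9, min_reads = 2L,
                            start_window = 100L, max_start_offset = 1500L,
                            mean_mode = "interval_mean", total_reads = NULL,
                            scale = 1e6, expressed_only = FALSE,
                            strand_aware = FALSE, trim_outliers = FALSE) {
  for (f in c(fastq, rm_out, sam, active_bed, inactive_bed, orf2_bed,
              exons, rmsk_track)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("input stage: missing input file: ", f)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  qc <- qc_reads(fastq,
                 fasta_out = if (is.null(out_dir)) NULL
                             else file.path(out_dir, "reads_filtered.fa"),
                 min_q = min_q, min_len = min_len)
  if (is.null(total_reads)) total_reads <- qc$n_after_q
  candidates <- names(qc$reads)

  selected <- select_reads_by_divergence(read_rm_out(rm_out),
                                         max_div = max_div)
  candidates <- intersect(candidates, selected)

  exon_gr <- if (is.null(exons)) NULL else read_exons(exons)
  refs <- prune_l1_references(read_bed(active_bed), read_bed(inactive_bed),
                              read_bed(orf2_bed), exons = exon_gr)
  if (!is.null(rmsk_track)) {
    track_gr <- read_rmsk_track(rmsk_track)
    refs$active <- annotate_subfamily(refs$active, track_gr)
  }
  regions <- c(refs$active, refs$inactive, refs$orf2)

  aln <- read_primary_alignments(sam)
  n_primary <- length(aln)
  aln <- aln[names(aln) %in% candidates]
  contained <- filter_by_containment(aln, regions, min_frac = min_frac)
  assign_tab <- read_locus_table(contained)

  lf <- apply_locus_filters(assign_tab, regions, min_reads = min_reads,
                            start_window = start_window,
                            max_start_offset = max_start_offset,
                            strand_aware = strand_aware,
                            trim_outliers = trim_outliers)
  kept_key <- paste(lf$reads$read_id, lf$reads$uid, lf$reads$start0)
  aln_key <- paste(names(contained), S4Vectors::mcols(contained)$locus_uid,
                   BiocGenerics::start(contained) - 1L)
  aln_kept <- contained[aln_key %in% kept_key]

  quant <- quantify_loci(aln_kept, regions, total_reads,
                         kept_uids = lf$verdicts$uid[lf$verdicts$kept],
                         mode = mean_mode, scale = scale)
  summary <- category_summary(quant$loci, expressed_only = expressed_only)
  subfam <- subfamily_report(quant$loci)

  stats <- data.frame(
    stage = c("input_reads", "after_quality", "after_length",
              "after_divergence", "primary_alignments", "after_containment",
              "after_locus_filters"),
    n = c(qc$n_input, qc$n_after_q, length(qc$reads), length(candidates),
          n_primary, length(contained), length(aln_kept)),
    stringsAsFactors = FALSE
  )

  if (!is.null(out_dir)) {
    write_bedgraph(quant$track, file.path(out_dir, "coverage.bg"))
    write.table(quant$loci, file.path(out_dir, "locus_expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summary, file.path(out_dir, "category_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(subfam, file.path(out_dir, "subfamily_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(lf$verdicts, file.path(out_dir, "locus_verdicts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(stats, file.path(out_dir, "stage_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (cat in names(refs)) {
      write_bed(refs[[cat]], file.path(out_dir, paste0(cat, "_pruned.bed")))
    }
    yaml::write_yaml(
      list(thresholds = list(min_q = min_q, min_len = min_len,
                             max_div = max_div, min_frac = min_frac,
                             min_reads = min_reads,
                             start_window = start_window,
                             max_start_offset = max_start_offset,
                             scale = scale, mean_mode = mean_mode),
           total_reads_convention = "reads passing the quality filter",
           total_reads = total_reads),
      file.path(out_dir, "run_log.yaml")
    )
  }

  list(stats = stats, refs = refs, verdicts = lf$verdicts,
       kept_reads = lf$reads, track = quant$track, loci = quant$loci,
       summary = summary, subfamily = subfam, total_reads = total_reads)
}
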