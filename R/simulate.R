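#' Default simulation plan
#'
#' Builds the locus and read plan for a fully synthetic L1 long-read dataset.
#' The default plan contains 15 reference loci across the three L1 categories
#' and 34 reads, arranged so that every pipeline filter has at least one decoy
#' that fails it and one near-boundary case that passes it:
#' \itemize{
#'   \item read QC: a 999-bp read (dropped) and a 1000-bp read (kept); a
#'     mean-Q 5 read (dropped);
#'   \item divergence selection: reads at 9.9\% (kept) and 10.0\% (dropped)
#'     divergence; a SINE/Alu-annotated read (dropped); a read with one 25\%
#'     and one 4\% hit (kept);
#'   \item reference pruning: an active locus overlapping an inactive locus
#'     by 1 bp and an active locus overlapping an exon (both removed);
#'   \item containment: reads at exactly 0.90 (kept) and 0.89 (dropped);
#'   \item locus filters: loci with 1 read, with a start deviating by 101 bp,
#'     and with a modal start 1501 bp into the element (all removed), next to
#'     boundary twins at 2 reads, 100 bp and 1500 bp (all kept);
#'   \item alignment parsing: one secondary SAM record (skipped);
#'   \item one spliced read (CIGAR `N`) for split-aware coverage.
#' }
#' Reads are planted at the locus 5' end plus a small uniform jitter, the
#' geometry long-read L1 transcripts show when transcription starts at the
#' element promoter.
#'
#' @param seed Integer seed; the plan (jitter draws) and all downstream
#'   sequence generation are deterministic given the seed.
#' @return A list with `seed`, `genome` (data.frame name/length), `loci`,
#'   `reads`, `exons`, `track` (RepeatMasker-track rows) and `truth_loci` /
#'   `truth_reads` tables.
#' @export
default_sim_config <- function(seed = 1L) {
  set.seed(seed)
  genome <- data.frame(name = c("chrS1", "chrS2"),
                       length = c(100000L, 100000L),
                       stringsAsFactors = FALSE)
  L <- 6000L
  loci <- rbind(
    data.frame(uid = paste0("ACT-", 1:8), category = "active",
               chrom = "chrS1", start0 = seq(2000L, by = 8000L, length.out = 8),
               length = L, strand = "+",
               subfamily = c("L1HS", "L1PA2", "L1HS", "L1HS", "L1PA2",
                             "L1HS", "L1HS", "L1PA2"),
               stringsAsFactors = FALSE),
    data.frame(uid = "ACT-11", category = "active", chrom = "chrS1",
               start0 = 66000L, length = L, strand = "+", subfamily = "L1HS"),
    data.frame(uid = c("ACT-9", "ACT-10"), category = "active",
               chrom = "chrS2", start0 = c(2000L, 10000L), length = L,
               strand = "+", subfamily = "L1HS"),
    data.frame(uid = c("INA-1", "INA-2"), category = "inactive",
               chrom = "chrS2", start0 = c(24000L, 15999L), length = L,
               strand = "+", subfamily = NA_character_),
    data.frame(uid = c("ORF-1", "ORF-2"), category = "orf2",
               chrom = "chrS2", start0 = c(32000L, 40000L), length = L,
               strand = "+", subfamily = NA_character_)
  )
  locus_start <- function(uid) loci$start0[match(uid, loci$uid)]
  jit <- function(n) sample.int(51L, n, replace = TRUE) - 1L

  rd <- function(id, uid, start0, len, q = 12L, div = 5, cigar = NA,
                 rm_class = "LINE/L1", rm_name = "L1HS", secondary_at = NA) {
    data.frame(read_id = id, uid = uid, start0 = start0, length = len,
               q = q, div = div, cigar = cigar, rm_class = rm_class,
               rm_name = rm_name, secondary_at = secondary_at,
               stringsAsFactors = FALSE)
  }
  j <- jit(6)
  reads <- rbind(
    # ACT-1: three normal reads, a 1000-bp boundary read, a 999-bp decoy,
    # a low-quality decoy; r03 gets a secondary record at ACT-4
    rd("r01", "ACT-1", 2000L + j[1], 3000L, div = 25),  # second 4% hit added below
    rd("r02", "ACT-1", 2000L + j[2], 3000L),
    rd("r03", "ACT-1", 2000L + j[3], 3000L, secondary_at = 26000L),
    rd("r04", "ACT-1", 2000L + j[4], 1000L),
    rd("r05", "ACT-1", 2000L + j[5], 999L),
    rd("r06", "ACT-1", 2000L + j[6], 3000L, q = 5L),
    # ACT-2: divergence boundary pass (9.9) plus a SINE decoy
    rd("r07", "ACT-2", 10000L, 3000L, div = 9.9, rm_name = "L1PA2"),
    rd("r08", "ACT-2", 10000L, 3000L, div = 9.9, rm_name = "L1PA2"),
    rd("r09", "ACT-2", 10000L, 3000L, div = 2.0, rm_class = "SINE/Alu",
       rm_name = "AluY"),
    # ACT-3: both reads at the 10.0 divergence boundary (dropped)
    rd("r10", "ACT-3", 18000L, 3000L, div = 10.0),
    rd("r11", "ACT-3", 18000L, 3000L, div = 10.0),
    # ACT-4: single-read locus
    rd("r12", "ACT-4", 26000L, 3000L),
    # ACT-5: one start deviating by 101 bp
    rd("r13", "ACT-5", 34000L, 3000L, rm_name = "L1PA2"),
    rd("r14", "ACT-5", 34000L, 3000L, rm_name = "L1PA2"),
    rd("r15", "ACT-5", 34101L, 3000L, rm_name = "L1PA2"),
    # ACT-6: deviation of exactly 100 bp (kept)
    rd("r16", "ACT-6", 42000L, 3000L),
    rd("r17", "ACT-6", 42000L, 3000L),
    rd("r18", "ACT-6", 42100L, 3000L),
    # ACT-7: modal start 1501 bp into the element (removed)
    rd("r19", "ACT-7", 51501L, 3000L),
    rd("r20", "ACT-7", 51501L, 3000L),
    # ACT-8: modal start exactly 1500 bp in (kept)
    rd("r21", "ACT-8", 59500L, 3000L, rm_name = "L1PA2"),
    rd("r22", "ACT-8", 59500L, 3000L, rm_name = "L1PA2"),
    # ACT-11: containment 0.90 kept twice, 0.89 dropped once
    rd("r23", "ACT-11", 65700L, 3000L),
    rd("r24", "ACT-11", 65700L, 3000L),
    rd("r25", "ACT-11", 65670L, 3000L),
    # INA-1: two plain reads and one spliced read
    rd("r26", "INA-1", 24000L, 3000L, rm_name = "L1PA7"),
    rd("r27", "INA-1", 24000L, 3000L, rm_name = "L1PA7"),
    rd("r28", "INA-1", 24040L, 2900L, cigar = "1450M100N1450M",
       rm_name = "L1PA7"),
    # INA-2 (overlapped 1 bp by ACT-10, which pruning removes)
    rd("r29", "INA-2", 16000L, 3000L, rm_name = "L1PA7"),
    rd("r30", "INA-2", 16000L, 3000L, rm_name = "L1PA7"),
    # ACT-9: exon-overlapping locus, removed at reference prep
    rd("r31", "ACT-9", 2000L, 3000L),
    rd("r32", "ACT-9", 2000L, 3000L),
    # ORF-1
    rd("r33", "ORF-1", 32000L, 3000L, rm_name = "L1PA4"),
    rd("r34", "ORF-1", 32000L, 3000L, rm_name = "L1PA4")
  )
  reads$chrom <- loci$chrom[match(reads$uid, loci$uid)]

  exons <- data.frame(
    chrom = c("chrS2", "chrS1", "chrS2"),
    start0 = c(7900L, 90000L, 90000L),
    end = c(8200L, 90500L, 90500L),
    name = c("EX-1", "EX-2", "EX-3"),
    stringsAsFactors = FALSE
  )

  act <- loci[loci$category == "active", ]
  track <- rbind(
    data.frame(genoName = act$chrom, genoStart = act$start0,
               genoEnd = act$start0 + act$length, strand = "+",
               repName = act$subfamily, repClass = "LINE", repFamily = "L1",
               stringsAsFactors = FALSE),
    data.frame(genoName = c("chrS1", "chrS1", "chrS2", "chrS1"),
               genoStart = c(3000L, 80000L, 80000L, 86000L),
               genoEnd = c(7000L, 84500L, 84501L, 86300L),
               strand = c("+", "+", "-", "+"),
               repName = c("L1PA3", "L1MA1", "L1MB1", "AluY"),
               repClass = c("LINE", "LINE", "LINE", "SINE"),
               repFamily = c("L1", "L1", "L1", "Alu"))
  )

  stage <- rep("pass", nrow(reads))
  stage[reads$read_id == "r05"] <- "fail_qc_len"
  stage[reads$read_id == "r06"] <- "fail_qc_q"
  stage[reads$read_id %in% c("r10", "r11")] <- "fail_divergence"
  stage[reads$read_id == "r09"] <- "fail_class"
  stage[reads$read_id == "r25"] <- "fail_containment"
  stage[reads$read_id %in% c("r31", "r32")] <- "fail_containment"
  stage[reads$read_id %in% c("r12", "r13", "r14", "r15", "r19", "r20")] <-
    "locus_removed"
  truth_reads <- data.frame(read_id = reads$read_id, uid = reads$uid,
                            stage = stage, stringsAsFactors = FALSE)

  truth_loci <- data.frame(
    uid = loci$uid, category = loci$category,
    in_reference = !(loci$uid %in% c("ACT-9", "ACT-10")),
    reason = "ok", surviving_reads = 0L, stringsAsFactors = FALSE
  )
  rs <- c("ACT-9" = "exon_overlap", "ACT-10" = "overlaps_inactive",
          "ACT-3" = "too_few_reads", "ACT-4" = "too_few_reads",
          "ORF-2" = "too_few_reads", "ACT-5" = "inconsistent_starts",
          "ACT-7" = "start_too_far")
  truth_loci$reason[match(names(rs), truth_loci$uid)] <- rs
  surv <- c("ACT-1" = 4L, "ACT-2" = 2L, "ACT-6" = 3L, "ACT-8" = 2L,
            "ACT-11" = 2L, "INA-1" = 3L, "INA-2" = 2L, "ORF-1" = 2L)
  truth_loci$surviving_reads[match(names(surv), truth_loci$uid)] <- surv

  list(seed = seed, genome = genome, loci = loci, reads = reads,
       exons = exons, track = track, truth_loci = truth_loci,
       truth_reads = truth_reads)
}

.sim_qual_char <- function(q) intToUtf8(q + 33L)

.sim_read_blocks <- function(start0, cigar, length) {
  # reference-consuming blocks (1-based) of a planted read
  if (is.na(cigar)) {
    return(data.frame(start = start0 + 1L, end = start0 + length))
  }
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSH=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  pos <- start0 + 1L
  out <- NULL
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "=", "X", "D")) {
      out <- rbind(out, data.frame(start = pos, end = pos + n[k] - 1L))
      pos <- pos + n[k]
    } else if (op[k] == "N") {
      pos <- pos + n[k]
    }
  }
  out
}

#' Generate a ground-truthed synthetic L1 long-read bundle
#'
#' Materializes a [default_sim_config()] plan (or a custom one of the same
#' shape) into files on disk: toy genome FASTA, the three L1 category BEDs,
#' exon BED, RepeatMasker genome-track TSV, LINE consensus FASTA, reads
#' FASTQ, RepeatMasker `.out` annotation of the reads, SAM alignments
#' (written directly from the planted geometry, so no aligner is needed), and
#' the truth tables. Byte-identical output for a fixed seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed, forwarded to [default_sim_config()].
#' @param config A simulation plan; defaults to `default_sim_config(seed)`.
#' @return A list with `dir`, a `paths` list (genome, active_bed,
#'   inactive_bed, orf2_bed, exons_bed, rmsk_track, consensus, fastq, rm_out,
#'   sam, truth_loci, truth_reads), the `config`, and the truth tables.
#' @export
simulate_l1_bundle <- function(out_dir, seed = 1L,
                               config = default_sim_config(seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  bad <- cfg$loci$start0 + cfg$loci$length >
    cfg$genome$length[match(cfg$loci$chrom, cfg$genome$name)]
  if (any(bad)) {
    stop("simulated loci exceed genome bounds: ",
         paste(cfg$loci$uid[bad], collapse = ", "))
  }
  set.seed(cfg$seed)
  genome <- Biostrings::DNAStringSet(vapply(cfg$genome$length, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1)))
  names(genome) <- cfg$genome$name

  p <- list(
    genome = file.path(out_dir, "genome.fa"),
    active_bed = file.path(out_dir, "active.bed"),
    inactive_bed = file.path(out_dir, "inactive.bed"),
    orf2_bed = file.path(out_dir, "orf2.bed"),
    exons_bed = file.path(out_dir, "exons.bed"),
    rmsk_track = file.path(out_dir, "rmsk_track.tsv"),
    consensus = file.path(out_dir, "line_consensus.fa"),
    fastq = file.path(out_dir, "reads.fastq"),
    rm_out = file.path(out_dir, "reads.fa.out"),
    sam = file.path(out_dir, "alignments.sam"),
    truth_loci = file.path(out_dir, "truth_loci.tsv"),
    truth_reads = file.path(out_dir, "truth_reads.tsv")
  )
  Biostrings::writeXStringSet(genome, p$genome)

  for (cat in L1_CATEGORIES) {
    sub <- cfg$loci[cfg$loci$category == cat, , drop = FALSE]
    dest <- switch(cat, active = p$active_bed, inactive = p$inactive_bed,
                   orf2 = p$orf2_bed)
    write.table(
      data.frame(sub$chrom, sub$start0, sub$start0 + sub$length, sub$uid,
                 0L, sub$strand),
      dest, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  write.table(
    data.frame(cfg$exons$chrom, cfg$exons$start0, cfg$exons$end,
               cfg$exons$name, 0L, "+"),
    p$exons_bed, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  write.table(cfg$track, p$rmsk_track, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)

  consensus <- Biostrings::DNAStringSet(vapply(c(6100L, 6050L, 300L),
    function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                      collapse = ""), character(1)))
  names(consensus) <- c("L1HS#LINE/L1", "L1PA2#LINE/L1", "AluY#SINE/Alu")
  Biostrings::writeXStringSet(consensus, p$consensus)

  rr <- cfg$reads
  seqs <- vapply(seq_len(nrow(rr)), function(i) {
    bl <- .sim_read_blocks(rr$start0[i], rr$cigar[i], rr$length[i])
    paste(vapply(seq_len(nrow(bl)), function(k) {
      as.character(Biostrings::subseq(genome[[rr$chrom[i]]],
                                      bl$start[k], bl$end[k]))
    }, character(1)), collapse = "")
  }, character(1))

  fq <- character(4L * nrow(rr))
  fq[seq(1, length(fq), 4)] <- paste0("@", rr$read_id)
  fq[seq(2, length(fq), 4)] <- seqs
  fq[seq(3, length(fq), 4)] <- "+"
  fq[seq(4, length(fq), 4)] <- vapply(seq_len(nrow(rr)), function(i) {
    strrep(.sim_qual_char(rr$q[i]), nchar(seqs[i]))
  }, character(1))
  writeLines(fq, p$fastq)

  # RepeatMasker .out: standard 3-line header, 15 columns
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    ""
  )
  rm_row <- function(score, div, id, qlen, name, cls, rowid) {
    sprintf("%5d %5.1f  0.0  0.0  %-10s %6d %6d (%d) + %-14s %-18s %5d %5d (0) %4d",
            score, div, id, 1L, qlen, 0L, name, cls, 1L, qlen, rowid)
  }
  rows <- character(0)
  rowid <- 0L
  for (i in seq_len(nrow(rr))) {
    rowid <- rowid + 1L
    rows <- c(rows, rm_row(1500L, rr$div[i], rr$read_id[i],
                           nchar(seqs[i]), rr$rm_name[i], rr$rm_class[i],
                           rowid))
    if (rr$read_id[i] == "r01") {
      # a second, low-divergence hit on the same read: any qualifying hit
      # suffices for selection
      rowid <- rowid + 1L
      rows <- c(rows, rm_row(2000L, 4.0, rr$read_id[i], nchar(seqs[i]),
                             "L1HS", "LINE/L1", rowid))
    }
  }
  writeLines(c(hdr, rows), p$rm_out)

  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", cfg$genome$name, cfg$genome$length)
  )
  ord <- order(rr$chrom, rr$start0)
  for (i in ord) {
    cigar <- if (is.na(rr$cigar[i])) paste0(rr$length[i], "M") else rr$cigar[i]
    qual <- strrep(.sim_qual_char(rr$q[i]), nchar(seqs[i]))
    sam <- c(sam, paste(rr$read_id[i], 0L, rr$chrom[i], rr$start0[i] + 1L,
                        60L, cigar, "*", 0L, 0L, seqs[i], qual, sep = "\t"))
    if (!is.na(rr$secondary_at[i])) {
      sam <- c(sam, paste(rr$read_id[i], 256L, rr$chrom[i],
                          rr$secondary_at[i] + 1L, 0L, cigar, "*", 0L, 0L,
                          "*", "*", sep = "\t"))
    }
  }
  writeLines(sam, p$sam)

  write.table(cfg$truth_loci, p$truth_loci, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cfg$truth_reads, p$truth_reads, sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(dir = out_dir, paths = p, config = cfg,
       truth_loci = cfg$truth_loci, truth_reads = cfg$truth_reads)
}

#' Compare pipeline output against the simulation truth
#'
#' Checks, for every simulated locus, that the pipeline's reference pruning,
#' verdict reason and surviving-read count match the truth tables of the
#' bundle.
#'
#' @param bundle Result of [simulate_l1_bundle()].
#' @param result Result of [run_l1_pipeline()] on that bundle.
#' @return A data.frame of mismatches (`uid`, `field`, `expected`,
#'   `observed`); zero rows means full truth recovery.
#' @export
verify_truth <- function(bundle, result) {
  tl <- bundle$truth_loci
  diffs <- data.frame(uid = character(0), field = character(0),
                      expected = character(0), observed = character(0),
                      stringsAsFactors = FALSE)
  note <- function(uid, field, exp, obs) {
    rbind(diffs, data.frame(uid = uid, field = field,
                            expected = as.character(exp),
                            observed = as.character(obs)))
  }
  v <- result$verdicts
  for (i in seq_len(nrow(tl))) {
    uid <- tl$uid[i]
    in_ref <- uid %in% v$uid
    if (in_ref != tl$in_reference[i]) {
      diffs <- note(uid, "in_reference", tl$in_reference[i], in_ref)
      next
    }
    if (!in_ref) next
    row <- v[v$uid == uid, ]
    if (row$reason != tl$reason[i]) {
      diffs <- note(uid, "reason", tl$reason[i], row$reason)
    }
    surv <- sum(result$kept_reads$uid == uid)
    if (surv != tl$surviving_reads[i]) {
      diffs <- note(uid, "surviving_reads", tl$surviving_reads[i], surv)
    }
  }
  diffs
}
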