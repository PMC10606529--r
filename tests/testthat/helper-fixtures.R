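# Shared fixture builders for the test suite. Everything is generated in
# code; external tools (samtools/bedtools) are only used as independent
# oracles.

# GRanges from 0-based half-open coordinates (BED convention)
gr0 <- function(chrom, start0, end, strand = "*", name = "") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end),
    strand = strand, name = rep_len(name, max(length(chrom), length(start0)))
  )
}

# 0-based half-open view of a GRanges, for asserting BED-style coordinates
as_bed_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

# Write a SAM file from a record table (read_id, flag, chrom, pos1, cigar)
write_test_sam <- function(records, seqlens, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  records <- records[order(match(records$chrom, names(seqlens)),
                           records$pos1), , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                  records$read_id, records$flag, records$chrom,
                  records$pos1, records$cigar)
  writeLines(c(hdr, body), path)
  path
}

sam_to_bam <- function(sam) {
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                   indexDestination = FALSE)
}

# One GAlignments from ad-hoc records
make_aln <- function(records, seqlens) {
  l1xpress::read_primary_alignments(write_test_sam(records, seqlens))
}

aln_rec <- function(read_id, chrom, pos1, cigar, flag = 0L) {
  data.frame(read_id = read_id, flag = flag, chrom = chrom, pos1 = pos1,
             cigar = cigar, stringsAsFactors = FALSE)
}

bt <- function(...) {
  system2("bedtools", c(...), stdout = TRUE)
}

# Random alignment fixture: small SAM/BAM plus well-separated L1 regions.
# Regions are separated by more than the largest possible read span so the
# union containment semantics coincide with the per-region semantics of the
# external oracle.
random_aln_case <- function(seed) {
  set.seed(seed)
  n_seqs <- sample(1:3, 1)
  seqlens <- setNames(sample(8000:20000, n_seqs, replace = TRUE),
                      paste0("chr", LETTERS[seq_len(n_seqs)]))
  n_reads <- sample(5:50, 1)
  recs <- do.call(rbind, lapply(seq_len(n_reads), function(i) {
    chrom <- sample(names(seqlens), 1)
    kind <- sample(c("m", "n", "d", "nd"), 1)
    m1 <- sample(80:400, 1)
    m2 <- sample(80:400, 1)
    cigar <- switch(kind,
      m = sprintf("%dM", m1),
      n = sprintf("%dM%dN%dM", m1, sample(50:500, 1), m2),
      d = sprintf("%dM%dD%dM", m1, sample(2:30, 1), m2),
      nd = sprintf("%dM%dD%dM%dN%dM", m1, sample(2:30, 1),
                   sample(80:200, 1), sample(50:400, 1), m2))
    span <- sum(as.integer(
      regmatches(cigar, gregexpr("\\d+(?=[MDN])", cigar, perl = TRUE))[[1]]
    ))
    pos1 <- sample(seq_len(max(1L, seqlens[[chrom]] - span - 1L)), 1)
    aln_rec(sprintf("r%03d", i), chrom, pos1, cigar)
  }))
  sam <- write_test_sam(recs, seqlens)
  bam <- sam_to_bam(sam)
  # well-separated regions: slots of 3600 with <=1500-wide regions inside
  regions <- do.call(rbind, lapply(names(seqlens), function(chrom) {
    slots <- seq(1, seqlens[[chrom]] - 3600, by = 3600)
    slots <- slots[sample(c(TRUE, FALSE), length(slots), replace = TRUE)]
    if (length(slots) == 0L) return(NULL)
    w <- sample(400:1500, length(slots), replace = TRUE)
    data.frame(chrom = chrom, start0 = slots, end = slots + w,
               stringsAsFactors = FALSE)
  }))
  bed <- tempfile(fileext = ".bed")
  if (is.null(regions)) {
    regions <- data.frame(chrom = names(seqlens)[1], start0 = 100L,
                          end = 900L, stringsAsFactors = FALSE)
  }
  regions <- regions[order(regions$chrom, regions$start0), , drop = FALSE]
  regions$name <- sprintf("L%03d", seq_len(nrow(regions)))
  write.table(regions[, c("chrom", "start0", "end", "name")], bed,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  list(sam = sam, bam = bam, bed = bed, seqlens = seqlens,
       regions = regions)
}

# parse bedtools genomecov -bga output
read_bg <- function(lines) {
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start0 = integer(0),
                      end = integer(0), depth = integer(0)))
  }
  f <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  setNames(f, c("chrom", "start0", "end", "depth"))
}

toy_path <- function(f) {
  system.file("extdata", "toy_l1base", f, package = "l1xpress")
}

sim_pipeline <- function(bundle, ...) {
  run_l1_pipeline(
    bundle$paths$fastq, bundle$paths$rm_out, bundle$paths$sam,
    bundle$paths$active_bed, bundle$paths$inactive_bed,
    bundle$paths$orf2_bed, exons = bundle$paths$exons_bed,
    rmsk_track = bundle$paths$rmsk_track, ...
  )
}
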