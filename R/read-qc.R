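#' Mean read quality on the Phred scale
#'
#' Per long-read basecaller convention the read-level quality is the Phred
#' transform of the mean per-base error probability,
#' \eqn{-10 \log_{10}(\mathrm{mean}_i\, 10^{-q_i/10})}, not the arithmetic
#' mean of the per-base Q scores.
#'
#' @param quals Numeric vector of per-base Phred scores of one read.
#' @return The read-level Phred score.
#' @examples
#' mean_read_q(c(10, 20)) # ~12.60
#' @export
mean_read_q <- function(quals) {
  if (length(quals) == 0L || anyNA(quals)) {
    stop("mean_read_q requires a non-empty vector of per-base qualities")
  }
  -10 * log10(mean(10^(-quals / 10)))
}

.read_mean_q <- function(fq) {
  # vectorized over a ShortReadQ: mean error probability per read
  m <- as(Biostrings::quality(fq), "matrix")
  -10 * log10(rowMeans(10^(-m / 10), na.rm = TRUE))
}

#' Quality- and length-filter long reads
#'
#' Keeps reads whose mean quality (see [mean_read_q()]) is at least `min_q`
#' and whose length is at least `min_len` bases. FASTA input carries no
#' qualities, so only the length test applies. Read order is preserved; the
#' filter is idempotent.
#'
#' @param reads A [ShortRead::ShortReadQ], a `DNAStringSet`, or a path to a
#'   FASTQ/FASTA file (gzip transparent).
#' @param min_q Minimum mean read quality (Phred), default 7.
#' @param min_len Minimum read length in bases, default 1000 (reads shorter
#'   than 1 kb are unlikely to inform on 4-6 kb L1 transcripts).
#' @return The surviving reads, same class as the input object.
#' @export
filter_reads <- function(reads, min_q = 7, min_len = 1000L) {
  if (is.character(reads)) {
    reads <- if (grepl("\\.f(ast)?q(\\.gz)?$", reads)) {
      ShortRead::readFastq(reads)
    } else {
      Biostrings::readDNAStringSet(reads)
    }
  }
  len <- if (is(reads, "ShortReadQ")) BiocGenerics::width(ShortRead::sread(reads))
         else BiocGenerics::width(reads)
  keep <- len >= min_len
  if (is(reads, "ShortReadQ") && length(reads) > 0L) {
    keep <- keep & .read_mean_q(reads) >= min_q
  }
  reads[keep]
}

#' Read-length summary statistics
#'
#' N50 is the length at which, summing read lengths in descending order, the
#' running total first reaches half of all sequenced bases; at least half of
#' the total bases reside in reads of length >= N50. The median of an
#' even-length list is the midpoint mean. An empty input yields all zeros.
#'
#' @param lengths Integer vector of read lengths.
#' @return A one-row data.frame: `n_reads`, `n50`, `median_len`, `n_ge_1kb`.
#' @examples
#' read_stats(c(1, 2, 3, 4, 5)) # N50 = 4, median = 3
#' @export
read_stats <- function(lengths) {
  if (length(lengths) == 0L) {
    return(data.frame(n_reads = 0L, n50 = 0, median_len = 0, n_ge_1kb = 0L))
  }
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  n50 <- s[which(cumsum(s) >= sum(s) / 2)[1L]]
  data.frame(
    n_reads = length(lengths),
    n50 = n50,
    median_len = median(as.numeric(lengths)),
    n_ge_1kb = sum(lengths >= 1000)
  )
}

#' File-level read QC
#'
#' Applies [filter_reads()] to a FASTQ/FASTA file, optionally writing the
#' survivors as FASTA (the format the downstream LINE-library mapping
#' consumes) and a one-row stats TSV of the post-filter read lengths.
#'
#' @param input Path to FASTQ or FASTA.
#' @param fasta_out Optional output FASTA path.
#' @param stats_out Optional output TSV path.
#' @inheritParams filter_reads
#' @return A list: `reads` (surviving reads), `stats` (see [read_stats()]),
#'   `n_input` (reads before filtering), `n_after_q` (reads surviving the
#'   quality filter alone, the pipeline's default normalization total).
#' @export
qc_reads <- function(input, fasta_out = NULL, stats_out = NULL,
                     min_q = 7, min_len = 1000L) {
  is_fastq <- grepl("\\.f(ast)?q(\\.gz)?$", input)
  raw <- if (is_fastq) ShortRead::readFastq(input)
         else Biostrings::readDNAStringSet(input)
  n_input <- length(raw)
  after_q <- if (is_fastq && n_input > 0L) sum(.read_mean_q(raw) >= min_q)
             else n_input
  kept <- filter_reads(raw, min_q = min_q, min_len = min_len)
  seqs <- if (is(kept, "ShortReadQ")) {
    s <- ShortRead::sread(kept)
    names(s) <- sub("\\s.*$", "", as.character(ShortRead::id(kept)))
    s
  } else {
    names(kept) <- sub("\\s.*$", "", names(kept))
    kept
  }
  stats <- read_stats(BiocGenerics::width(seqs))
  if (!is.null(fasta_out)) {
    Biostrings::writeXStringSet(seqs, fasta_out)
  }
  if (!is.null(stats_out)) {
    write.table(stats, stats_out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reads = seqs, stats = stats, n_input = n_input, n_after_q = after_q)
}
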