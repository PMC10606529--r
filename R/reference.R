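L1_CATEGORIES <- c("active", "inactive", "orf2")

#' Construct an L1 region set
#'
#' Attaches the category label, L1Base2 UID (taken from the BED name column
#' when no `uid` is supplied) and element length to a `GRanges` of L1
#' intervals. Categories follow L1Base2: `active` (FLI-L1, both ORFs intact),
#' `inactive` (FLnI-L1, full-length non-intact) and `orf2` (ORF2-L1, intact
#' only in ORF2).
#'
#' @param gr `GRanges` of L1 intervals.
#' @param category One of `"active"`, `"inactive"`, `"orf2"`.
#' @param uid Optional character vector of unique identifiers.
#' @return `GRanges` with mcols `uid`, `category`, `subfamily` (NA until
#'   [annotate_subfamily()]) and `length`.
#' @export
l1_regions <- function(gr, category, uid = NULL) {
  category <- match.arg(category, L1_CATEGORIES)
  stopifnot(is(gr, "GRanges"))
  if (is.null(uid)) {
    uid <- if (!is.null(gr$name) && any(nzchar(gr$name))) gr$name
           else paste0(toupper(substr(category, 1, 3)), "-", seq_along(gr))
  }
  blank <- is.na(uid) | !nzchar(uid)
  uid[blank] <- paste0(toupper(substr(category, 1, 3)), "-", which(blank))
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    uid = uid,
    category = category,
    subfamily = if (!is.null(gr$subfamily)) gr$subfamily else NA_character_,
    length = BiocGenerics::width(out)
  )
  out
}

#' Prune the three L1Base2 category references
#'
#' Reference preparation before quantification:
#' \enumerate{
#'   \item active regions overlapping any inactive region are removed whole;
#'   \item all three categories then have regions overlapping annotated exons
#'     removed whole.
#' }
#' All overlap tests are strand-blind and a single shared base counts as
#' overlap. Region categories never change and regions are never clipped.
#'
#' @param active,inactive,orf2 `GRanges` of the three L1Base2 category BEDs
#'   (e.g. from [read_bed()]).
#' @param exons `GRanges` of exon intervals (from [read_exons()]), or `NULL`
#'   to skip exon exclusion.
#' @return A named list of three pruned region sets (as [l1_regions()]
#'   objects): `active`, `inactive`, `orf2`.
#' @export
prune_l1_references <- function(active, inactive, orf2, exons = NULL) {
  act <- l1_regions(active, "active")
  ina <- l1_regions(inactive, "inactive")
  o2 <- l1_regions(orf2, "orf2")
  act <- subtract_overlapping(act, ina)
  if (!is.null(exons) && length(exons) > 0L) {
    act <- exclude_exon_overlaps(act, exons)
    ina <- exclude_exon_overlaps(ina, exons)
    o2 <- exclude_exon_overlaps(o2, exons)
  }
  list(active = act, inactive = ina, orf2 = o2)
}

#' Read a UCSC RepeatMasker genome-track table
#'
#' Reads the rmsk schema (TSV with at least `genoName`, `genoStart`,
#' `genoEnd`, `strand`, `repName`, `repClass`, `repFamily`; a header line is
#' auto-detected). `genoStart` is 0-based half-open as in the UCSC table.
#'
#' @param path Path to the TSV.
#' @return A `GRanges` with mcols `repName`, `repClass`, `repFamily`.
#' @export
read_rmsk_track <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("genoName", first, fixed = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE, comment.char = "",
                   quote = "")
  if (!has_header) {
    # headerless exports keep the rmsk column order
    cols <- c("genoName", "genoStart", "genoEnd", "strand",
              "repName", "repClass", "repFamily")
    if (ncol(df) < length(cols)) {
      stop("rmsk track needs >= 7 columns (",
           paste(cols, collapse = ", "), ")")
    }
    names(df)[seq_along(cols)] <- cols
  }
  strand <- ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  GenomicRanges::GRanges(
    seqnames = df$genoName,
    ranges = IRanges::IRanges(start = df$genoStart + 1L, end = df$genoEnd),
    strand = strand,
    repName = df$repName,
    repClass = df$repClass,
    repFamily = df$repFamily
  )
}

#' Build the custom LINE mapping library
#'
#' Combines (1) genomic LINE copies longer than `min_len` from a RepeatMasker
#' genome track (sequence extracted from the genome, reverse-complemented for
#' minus-strand rows) and (2) LINE consensus sequences, into the FASTA library
#' used to pre-select candidate reads by mapping.
#'
#' @param track `GRanges` from [read_rmsk_track()].
#' @param genome A [Biostrings::DNAStringSet], or a path to a genome FASTA.
#' @param consensus A `DNAStringSet` (or FASTA path) of repeat consensus
#'   sequences; entries named in RepeatMasker library style
#'   (`name#class/family`) are kept only when the class is LINE, unannotated
#'   entries are kept as-is.
#' @param min_len Minimum genomic element span in bases; the filter is strict
#'   (a span of exactly `min_len` is excluded). Default 4500.
#' @param out Optional path; when given the library is also written as FASTA.
#' @return A `DNAStringSet`; names are `repName:chrom:start-end` for genomic
#'   entries and the consensus identifier for consensus entries. The metadata
#'   column `source` distinguishes `genome_track` from `consensus` entries.
#' @export
build_line_library <- function(track, genome, consensus = NULL,
                               min_len = 4500L, out = NULL) {
  stopifnot(is(track, "GRanges"))
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  keep <- track$repClass == "LINE" & BiocGenerics::width(track) > min_len
  lines <- track[keep]
  missing <- setdiff(as.character(GenomicRanges::seqnames(lines)), names(genome))
  if (length(missing) > 0L) {
    stop("rmsk track references sequences absent from the genome: ",
         paste(unique(missing), collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(lines), function(i) {
    r <- lines[i]
    s <- Biostrings::subseq(genome[[as.character(GenomicRanges::seqnames(r))]],
                            BiocGenerics::start(r), BiocGenerics::end(r))
    if (as.character(BiocGenerics::strand(r)) == "-") {
      s <- Biostrings::reverseComplement(s)
    }
    s
  }))
  names(seqs) <- sprintf("%s:%s:%d-%d", lines$repName,
                         as.character(GenomicRanges::seqnames(lines)),
                         BiocGenerics::start(lines) - 1L,
                         BiocGenerics::end(lines))
  src <- rep("genome_track", length(seqs))
  if (!is.null(consensus)) {
    if (is.character(consensus)) {
      consensus <- Biostrings::readDNAStringSet(consensus)
    }
    ids <- sub("\\s.*$", "", names(consensus))
    cls <- ifelse(grepl("#", ids, fixed = TRUE), sub("^[^#]*#", "", ids), NA)
    keep_c <- is.na(cls) | grepl("^LINE", cls)
    consensus <- consensus[keep_c]
    names(consensus) <- ids[keep_c]
    seqs <- c(seqs, consensus)
    src <- c(src, rep("consensus", sum(keep_c)))
  }
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(source = src)
  if (!is.null(out)) {
    Biostrings::writeXStringSet(seqs, out)
  }
  seqs
}

#' Annotate L1 regions with their repeat subfamily
#'
#' Assigns to each region the `repName` (e.g. L1HS, L1PA2) of the long
#' (> `min_len` bp) RepeatMasker track row with the largest base overlap.
#' Ties go to the lexicographically smallest `repName`; regions with no
#' overlapping long track row keep `NA`.
#'
#' @param regions An [l1_regions()] `GRanges`.
#' @param track `GRanges` from [read_rmsk_track()].
#' @param min_len Minimum track-row span considered (strict), default 4500.
#' @return `regions` with the `subfamily` mcols column filled in.
#' @export
annotate_subfamily <- function(regions, track, min_len = 4500L) {
  stopifnot(is(regions, "GRanges"), is(track, "GRanges"))
  long <- track[BiocGenerics::width(track) > min_len]
  regions$subfamily <- NA_character_
  if (length(long) == 0L || length(regions) == 0L) {
    return(regions)
  }
  hits <- GenomicRanges::findOverlaps(regions, long, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(regions)
  }
  ov <- BiocGenerics::width(IRanges::pintersect(
    GenomicRanges::ranges(regions)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(long)[S4Vectors::subjectHits(hits)]
  ))
  nm <- long$repName[S4Vectors::subjectHits(hits)]
  for (q in unique(S4Vectors::queryHits(hits))) {
    sel <- S4Vectors::queryHits(hits) == q
    o <- ov[sel]
    n <- nm[sel]
    best <- n[o == max(o)]
    regions$subfamily[q] <- min(best)
  }
  regions
}
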