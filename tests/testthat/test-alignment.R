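test_that("only mapped, primary, non-supplementary records are parsed", {
  seqlens <- c(chrA = 5000L)
  recs <- rbind(
    aln_rec("p1", "chrA", 101, "100M"),
    aln_rec("sec", "chrA", 301, "100M", flag = 256L),
    aln_rec("sup", "chrA", 501, "100M", flag = 2048L),
    aln_rec("unm", "chrA", 0, "*", flag = 4L)
  )
  recs$pos1[recs$flag == 4L] <- 1L  # unmapped placeholder
  aln <- make_aln(recs, seqlens)
  expect_equal(names(aln), "p1")
  # SAM position 101 is 0-based start 100
  expect_equal(BiocGenerics::start(aln) - 1L, 100L)
  expect_equal(S4Vectors::mcols(aln)$mapq, 60L)
})

test_that("spans and blocks follow reference-consuming CIGAR geometry", {
  seqlens <- c(chrA = 5000L)
  aln <- make_aln(rbind(
    aln_rec("del", "chrA", 101, "50M10D50M"),
    aln_rec("spl", "chrA", 101, "50M1000N50M"),
    aln_rec("clip", "chrA", 1, "10S80M")
  ), seqlens)
  g <- alignment_blocks(aln)
  ord <- match(c("del", "spl", "clip"), names(g$span))
  sp <- as_bed_df(g$span)[ord, ]
  expect_equal(sp$start0, c(100L, 100L, 0L))
  expect_equal(sp$end, c(210L, 1200L, 80L))
  bl <- g$blocks[match(c("del", "spl", "clip"), names(g$blocks))]
  expect_equal(unname(lengths(bl)), c(1L, 2L, 1L))
  expect_equal(as_bed_df(bl[["spl"]])$start0, c(100L, 1150L))
  expect_equal(as_bed_df(bl[["del"]])$end, 210L)
})

test_that("containment fraction is span overlap over span length", {
  seqlens <- c(chrA = 10000L)
  aln <- make_aln(aln_rec("r", "chrA", 1, "1000M"), seqlens)
  expect_equal(containment_fraction(aln, gr0("chrA", 0, 900)), 0.9)
  expect_equal(containment_fraction(aln, gr0("chrA", 0, 6000)), 1.0)
  # union semantics: overlapping regions are not double counted
  expect_equal(containment_fraction(
    aln, gr0("chrA", c(0, 400), c(500, 950))), 0.95)
})

test_that("containment matches a per-base membership oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    case <- random_aln_case(seed)
    aln <- read_primary_alignments(case$bam)
    regions <- read_bed(case$bed)
    got <- containment_fraction(aln, regions)
    span <- as_bed_df(GenomicRanges::granges(aln))
    rg <- as_bed_df(regions)
    exp <- vapply(seq_len(nrow(span)), function(i) {
      bases <- span$start0[i]:(span$end[i] - 1L)
      inside <- rep(FALSE, length(bases))
      for (j in which(rg$chrom == span$chrom[i])) {
        inside <- inside | (bases >= rg$start0[j] & bases < rg$end[j])
      }
      mean(inside)
    }, numeric(1))
    expect_equal(got, exp, tolerance = 1e-12)
  }
})

test_that("containment is invariant to region permutation and splitting", {
  seqlens <- c(chrA = 10000L)
  aln <- make_aln(aln_rec("r", "chrA", 201, "2000M"), seqlens)
  whole <- gr0("chrA", c(0, 3000), c(1500, 4000))
  split <- gr0("chrA", c(0, 700, 3000, 3500), c(700, 1500, 3500, 4000))
  f1 <- containment_fraction(aln, whole)
  expect_equal(containment_fraction(aln, rev(whole)), f1)
  expect_equal(containment_fraction(aln, split), f1)
})

test_that("the 90% filter is inclusive and assigns the max-overlap locus", {
  seqlens <- c(chrA = 10000L)
  regions <- l1_regions(gr0("chrA", c(1000, 2000), c(2000, 2400),
                            name = c("LEFT", "RIGHT")), "active")
  # read [1300,2300): 700 in LEFT (70%), 300 in RIGHT (30%), total 100%
  both <- make_aln(aln_rec("b", "chrA", 1301, "1000M"), seqlens)
  kept <- filter_by_containment(both, regions)
  expect_equal(S4Vectors::mcols(kept)$locus_uid, "LEFT")

  # containment 0.90 kept, 0.89 dropped
  single <- l1_regions(gr0("chrA", 0, 900, name = "S"), "active")
  a <- make_aln(rbind(aln_rec("k", "chrA", 1, "900M100S"),
                      aln_rec("f", "chrA", 1, "1000M")), seqlens)
  f <- containment_fraction(a, single)
  expect_equal(unname(f[match(c("k", "f"), names(a))]), c(1, 0.9))
  wide <- l1_regions(gr0("chrA", 0, 890, name = "W"), "active")
  f2 <- containment_fraction(a, wide)
  expect_equal(unname(f2[names(a) == "f"]), 0.89)
  expect_equal(names(filter_by_containment(a, wide)), "k")
  kept2 <- filter_by_containment(a, single)
  expect_setequal(names(kept2), c("k", "f"))

  # no regions -> empty output
  expect_length(filter_by_containment(a, single[0]), 0L)
})

test_that("containment filtering agrees with bedtools intersect -f 0.9", {
  for (seed in 101:110) {
    case <- random_aln_case(seed)
    aln <- read_primary_alignments(case$bam)
    regions <- l1_regions(read_bed(case$bed), "active")
    mine <- filter_by_containment(aln, regions, min_frac = 0.9)
    obam <- tempfile(fileext = ".bam")
    system2("bedtools",
                      c("intersect", "-u", "-f", "0.9", "-a", case$bam,
                        "-b", case$bed),
                      stdout = obam)
    o <- Rsamtools::scanBam(obam,
      param = Rsamtools::ScanBamParam(what = c("qname", "pos")))[[1]]
    expect_equal(sort(paste(names(mine), BiocGenerics::start(mine))),
                 sort(paste(o$qname, o$pos)))
  }
})
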