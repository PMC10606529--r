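toy_refs <- function() {
  prune_l1_references(read_bed(toy_path("active.bed")),
                      read_bed(toy_path("inactive.bed")),
                      read_bed(toy_path("orf2.bed")),
                      exons = read_bed(toy_path("exons.bed")))
}

test_that("toy reference pruning keeps exactly the hand-computed survivors", {
  refs <- toy_refs()
  expect_equal(sort(refs$active$uid),
               c("A01", "A03", "A04", "A06", "A08", "A09", "A10"))
  expect_equal(sum(grepl("^I", refs$inactive$uid)), 12L)
  expect_false(any(c("I01", "I02") %in% refs$inactive$uid))
  expect_equal(sort(refs$orf2$uid), c("O01", "O02", "O03", "O05", "O06"))
})

test_that("pruning never changes category, coordinates or clips regions", {
  refs <- toy_refs()
  full_active <- l1_regions(read_bed(toy_path("active.bed")), "active")
  expect_true(all(refs$active$uid %in% full_active$uid))
  m <- match(refs$active$uid, full_active$uid)
  expect_equal(BiocGenerics::start(refs$active), BiocGenerics::start(full_active)[m])
  expect_equal(BiocGenerics::width(refs$active), BiocGenerics::width(full_active)[m])
  expect_true(all(refs$active$category == "active"))
  expect_true(all(refs$inactive$category == "inactive"))
  expect_true(all(refs$orf2$category == "orf2"))
})

test_that("l1_regions carries uid, category and length invariants", {
  gr <- gr0("chr1", c(0, 100), c(50, 400), name = c("U1", ""))
  reg <- l1_regions(gr, "inactive")
  expect_equal(reg$uid[1], "U1")
  expect_match(reg$uid[2], "^INA-")  # blank names get generated uids
  expect_equal(reg$length, c(50L, 300L))
  expect_error(l1_regions(gr, "bogus"))
})

make_genome <- function() {
  set.seed(42)
  g <- Biostrings::DNAStringSet(c(
    paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = ""),
    paste(sample(c("A", "C", "G", "T"), 12000, replace = TRUE), collapse = "")
  ))
  names(g) <- c("c1", "c2")
  g
}

test_that("LINE library takes only LINE rows strictly longer than min_len", {
  genome <- make_genome()
  track <- GenomicRanges::GRanges(
    c("c1", "c1", "c2", "c1"),
    IRanges::IRanges(start = c(1, 5001, 1, 12001),
                     width = c(4500, 4501, 6000, 5000)),
    strand = c("+", "+", "+", "-"),
    repName = c("L1M", "L1HS", "AluSINE", "L1PA2"),
    repClass = c("LINE", "LINE", "SINE", "LINE"),
    repFamily = c("L1", "L1", "Alu", "L1")
  )
  lib <- build_line_library(track, genome)
  expect_equal(length(lib), 2L)  # 4500 excluded (strict), SINE excluded
  expect_match(names(lib)[1], "^L1HS:")
  # minus-strand entry is reverse-complemented
  raw <- Biostrings::subseq(genome[["c1"]], 12001, 17000)
  expect_equal(as.character(lib[[2]]),
               as.character(Biostrings::reverseComplement(raw)))
})

test_that("LINE consensus entries are appended, non-LINE classes dropped", {
  genome <- make_genome()
  track <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, width = 5000),
                                  strand = "+", repName = "L1HS",
                                  repClass = "LINE", repFamily = "L1")
  cons <- Biostrings::DNAStringSet(c("ACGTACGT", "GGGCCC", "TTTTAA"))
  names(cons) <- c("L1HS#LINE/L1", "AluY#SINE/Alu", "L1PB#LINE/L1")
  lib <- build_line_library(track, genome, consensus = cons)
  expect_equal(length(lib), 3L)
  expect_setequal(S4Vectors::mcols(lib)$source,
                  c("genome_track", "consensus", "consensus"))
  expect_false("AluY#SINE/Alu" %in% names(lib))
})

test_that("library construction fails on sequences absent from the genome", {
  track <- GenomicRanges::GRanges("chrMissing",
                                  IRanges::IRanges(1, width = 5000),
                                  strand = "+", repName = "L1HS",
                                  repClass = "LINE", repFamily = "L1")
  expect_error(build_line_library(track, make_genome()), "chrMissing")
})

test_that("subfamily is the largest-overlap long track row", {
  regions <- l1_regions(gr0("c1", c(0, 50000), c(6000, 56000)), "active")
  track <- GenomicRanges::GRanges(
    "c1",
    IRanges::IRanges(start = c(1, 5951, 30000),
                     width = c(5000, 5000, 5000)),
    strand = "+",
    repName = c("L1HS", "L1PA2", "L1PA4"),
    repClass = "LINE", repFamily = "L1"
  )
  out <- annotate_subfamily(regions, track)
  # 5000-bp overlap with L1HS beats 50-bp overlap with L1PA2
  expect_equal(out$subfamily, c("L1HS", NA))

  # brute-force oracle over random geometries
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6
    rs <- sample(0:20000, n)
    regions <- l1_regions(gr0("c1", rs, rs + 6000), "active")
    ts <- sample(0:20000, 8)
    track <- GenomicRanges::GRanges(
      "c1", IRanges::IRanges(start = ts + 1, width = sample(4501:8000, 8)),
      strand = "+", repName = sample(c("L1HS", "L1PA2", "L1PA3"), 8, TRUE),
      repClass = "LINE", repFamily = "L1")
    got <- annotate_subfamily(regions, track)$subfamily
    exp <- vapply(seq_len(n), function(i) {
      ov <- pmax(0, pmin(BiocGenerics::end(regions)[i], BiocGenerics::end(track)) -
                   pmax(BiocGenerics::start(regions)[i], BiocGenerics::start(track)) + 1)
      if (all(ov == 0)) return(NA_character_)
      cand <- track$repName[ov == max(ov)]
      sort(cand)[1]
    }, character(1))
    expect_equal(got, exp)
  }
})

test_that("equal subfamily overlaps break ties lexicographically", {
  regions <- l1_regions(gr0("c1", 1000, 7000), "active")
  track <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(start = c(1001, 1001), width = 5000),
    strand = "+", repName = c("L1PA2", "L1HS"),
    repClass = "LINE", repFamily = "L1")
  expect_equal(annotate_subfamily(regions, track)$subfamily, "L1HS")
})
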