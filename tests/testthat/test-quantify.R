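test_that("split coverage emits zero intervals and splits at N", {
  aln <- make_aln(aln_rec("r", "chrA", 101, "50M1000N50M"),
                  c(chrA = 2000L))
  track <- genome_coverage(aln)
  expect_equal(track,
               data.frame(chrom = "chrA",
                          start0 = c(0L, 100L, 150L, 1150L, 1200L),
                          end = c(100L, 150L, 1150L, 1200L, 2000L),
                          depth = c(0L, 1L, 0L, 1L, 0L)))
})

test_that("coverage is additive and tiles empty sequences with zeros", {
  two <- make_aln(rbind(aln_rec("a", "chrA", 101, "50M1000N50M"),
                        aln_rec("b", "chrA", 101, "50M1000N50M")),
                  c(chrA = 2000L, chrB = 500L))
  track <- genome_coverage(two)
  a <- track[track$chrom == "chrA", ]
  expect_equal(a$depth, c(0L, 2L, 0L, 2L, 0L))
  expect_equal(a$start0, c(0L, 100L, 150L, 1150L, 1200L))
  b <- track[track$chrom == "chrB", ]
  expect_equal(unname(as.list(b)),
               list("chrB", 0L, 500L, 0L))
  none <- make_aln(aln_rec("a", "chrA", 101, "50M")[0, ], c(chrA = 300L))
  expect_equal(genome_coverage(none)$depth, 0L)
})

test_that("total covered bases equal the summed aligned segment lengths", {
  for (seed in 21:25) {
    case <- random_aln_case(seed)
    aln <- read_primary_alignments(case$bam)
    track <- genome_coverage(aln)
    segs <- unlist(GenomicAlignments::grglist(aln, drop.D.ranges = TRUE))
    expect_equal(sum(track$depth * (track$end - track$start0)),
                 sum(BiocGenerics::width(segs)))
  }
})

test_that("coverage and interval means match the bedtools oracles", {
  for (seed in 31:35) {
    case <- random_aln_case(seed)
    aln <- read_primary_alignments(case$bam)
    mine <- genome_coverage(aln)
    oracle <- read_bg(bt("genomecov", "-ibam", case$bam, "-bga", "-split"))
    expect_equal(mine, oracle)

    bg <- tempfile(fileext = ".bg")
    write_bedgraph(mine, bg)
    map <- bt("map", "-a", case$bed, "-b", bg, "-c", "4", "-o", "mean",
              "-null", "0")
    exp_mean <- as.numeric(vapply(strsplit(map, "\t"), tail, character(1), 1))
    got <- mean_coverage(mine, read_bed(case$bed))
    expect_equal(got, exp_mean, tolerance = 1e-9)
  }
})

test_that("interval and base means implement their documented semantics", {
  track <- data.frame(chrom = "c", start0 = c(0L, 10L), end = c(10L, 20L),
                      depth = c(0L, 5L))
  reg <- gr0("c", 5, 15)
  expect_equal(mean_coverage(track, reg, "interval_mean"), 2.5)
  expect_equal(mean_coverage(track, reg, "base_mean"), 2.5)

  track2 <- data.frame(chrom = "c", start0 = c(0L, 90L), end = c(90L, 100L),
                       depth = c(0L, 9L))
  reg2 <- gr0("c", 0, 100)
  expect_equal(mean_coverage(track2, reg2, "interval_mean"), 4.5)
  expect_equal(mean_coverage(track2, reg2, "base_mean"), 0.9)

  # constant-depth region gives the depth in both modes
  expect_equal(mean_coverage(track2, gr0("c", 10, 50), "interval_mean"),
               mean_coverage(track2, gr0("c", 10, 50), "base_mean"))
  expect_error(mean_coverage(track2, gr0("missing", 0, 10)), "absent")
})

test_that("normalization scales by total reads in millions", {
  expect_equal(normalize_expression(2.0, 1e6), 2.0)
  expect_equal(normalize_expression(0, 123), 0)
  expect_equal(normalize_expression(3.0, 5e5), 6.0)
  expect_error(normalize_expression(1, 0))
})

test_that("the length-weighted category average follows the formula", {
  expect_equal(weighted_average(c(6000, 4000), c(2.0, 0.5)), 1.4)
  expect_equal(weighted_average(rep(3000, 7), rep(0.77, 7)), 0.77)
  # zero loci dilute: one expressed locus among nine silent ones
  expect_equal(weighted_average(rep(800, 10), c(10, rep(0, 9))), 1.0)
  expect_equal(weighted_average(rep(800, 10), c(10, rep(0, 9)),
                                expressed_only = TRUE), 10)
  expect_error(weighted_average(numeric(0), numeric(0)))
})

test_that("category summaries stay within the per-locus value range", {
  set.seed(9)
  loci <- data.frame(
    uid = sprintf("u%d", 1:30),
    category = sample(c("active", "inactive", "orf2"), 30, replace = TRUE),
    subfamily = NA_character_,
    length = sample(4500:8000, 30),
    mean_cov = runif(30, 0, 3)
  )
  loci$normalized <- loci$mean_cov * 2
  cs <- category_summary(loci)
  for (i in seq_len(nrow(cs))) {
    vals <- loci$normalized[loci$category == cs$category[i]]
    expect_gte(cs$weighted_average[i], min(vals))
    expect_lte(cs$weighted_average[i], max(vals))
    expect_equal(cs$n_expressed[i], sum(vals > 0))
  }
})

test_that("duplicating every read doubles coverage means, ratios unchanged", {
  recs <- rbind(aln_rec("a", "chrA", 101, "300M"),
                aln_rec("b", "chrA", 501, "200M100N300M"),
                aln_rec("c", "chrB", 51, "400M"))
  dup <- recs; dup$read_id <- paste0(recs$read_id, "_dup")
  seqlens <- c(chrA = 3000L, chrB = 2000L)
  one <- make_aln(recs, seqlens)
  two <- make_aln(rbind(recs, dup), seqlens)
  regions <- gr0(c("chrA", "chrB"), c(100, 0), c(1200, 500))
  m1 <- mean_coverage(genome_coverage(one), regions)
  m2 <- mean_coverage(genome_coverage(two), regions)
  expect_equal(m2, 2 * m1)
  n1 <- normalize_expression(m1, 3)
  n2 <- normalize_expression(m2, 6)
  expect_equal(n1[1] / n1[2], n2[1] / n2[2])
})

test_that("subfamily report counts expressed active loci per family", {
  loci <- data.frame(
    uid = sprintf("u%d", 1:6),
    category = "active",
    subfamily = c("L1HS", "L1HS", "L1HS", "L1PA2", "L1PA3", NA),
    length = 6000,
    mean_cov = c(1, 1, 1, 1, 0, 0)
  )
  loci$normalized <- loci$mean_cov
  rep1 <- subfamily_report(loci)
  expect_equal(rep1$n_expressed, c(3L, 1L, 0L))
  expect_equal(rep1$pct, c(75, 25, 0))

  loci$normalized <- 0
  rep0 <- subfamily_report(loci)
  expect_equal(rep0$n_expressed, rep(0L, 3))
  expect_equal(rep0$pct, rep(0, 3))

  # unset subfamily counts under "other"
  loci$normalized <- c(0, 0, 0, 0, 0, 2)
  expect_equal(subfamily_report(loci)$n_expressed, c(0L, 0L, 1L))
})
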