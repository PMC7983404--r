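test_that("BED reading maps fields, preserves order and rejects bad lines", {
  f <- tmpfile(c("track name=test", "# comment",
                 "chr2L\t100\t350", "chr3R\t0\t10"), ".bed")
  iv <- read_bed(f)
  expect_equal(iv$chrom, c("chr2L", "chr3R"))
  expect_equal(iv$start, c(100, 0))
  expect_equal(iv$end, c(350, 10))

  expect_equal(nrow(read_bed(tmpfile(character(0)))), 0)
  expect_error(read_bed(tmpfile("chr2L\t350\t100")), "line 1")
  expect_error(read_bed(tmpfile(c("chr1\t0\t5", "chr1\t7"))), "line 2")
})

test_that("narrowPeak round trip is the identity on modeled fields", {
  pk <- peaks(chrom = c("chr2L", "chr2L", "chr3R"),
              start = c(100, 900, 50), end = c(600, 1400, 550),
              summit_offset = c(125, 250, 499),
              score = c(5.5, 12.25, 3), p_value = c(1e-6, 1e-13, 1e-3))
  f <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, f)
  back <- read_narrowpeak(f)
  expect_equal(back$chrom, pk$chrom)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$summit_offset, pk$summit_offset)
  expect_equal(back$score, pk$score)
  expect_equal(back$p_value, pk$p_value, tolerance = 1e-12)
})

test_that("narrowPeak summit -1 falls back to the midpoint with a warning", {
  f <- tmpfile("chr2L\t100\t600\tp1\t0\t.\t5\t3\t-1\t-1")
  expect_warning(pk <- read_narrowpeak(f), "midpoint")
  expect_equal(pk$summit_offset, 250)
  # summit outside the interval is a parse error
  f2 <- tmpfile("chr2L\t100\t600\tp1\t0\t.\t5\t3\t-1\t500")
  expect_error(read_narrowpeak(f2), "summit offset")
  f3 <- tmpfile("chr2L\t100\t600\tp1\t0\t.\t5\t3\t-1")
  expect_error(read_narrowpeak(f3), "expected 10 columns")
})

test_that("summit_window returns +/- flank, clips at bounds, validates flank", {
  pk <- peaks("chr3R", 9000, 11000, 1000, 10, 1e-5)  # absolute summit 10000
  w <- summit_window(pk, 250)
  expect_equal(w$start, 9750)
  expect_equal(w$end, 10250)

  pk2 <- peaks("chr2L", 0, 400, 100, 10, 1e-5)       # summit at 100
  w2 <- summit_window(pk2, 250, chrom_sizes = c(chr2L = 1e4))
  expect_equal(c(w2$start, w2$end), c(0, 350))

  w3 <- summit_window(pk2, 250, chrom_sizes = c(chr2L = 200))
  expect_equal(c(w3$start, w3$end), c(0, 200))       # right clip too
  expect_error(summit_window(pk, 0), "flank")
})

test_that("overlap semantics are strict half-open", {
  a <- genomic_intervals("chr1", 100, 200)
  expect_true(interval_overlaps(a, genomic_intervals("chr1", 199, 300)))
  expect_false(interval_overlaps(a, genomic_intervals("chr1", 200, 300)))
  expect_false(interval_overlaps(a, genomic_intervals("chr2", 150, 160)))
  # overlap length 10 < min_overlap 20
  expect_false(interval_overlaps(a, genomic_intervals("chr1", 150, 160),
                                 min_overlap = 20))
  expect_true(interval_overlaps(a, genomic_intervals("chr1", 150, 160),
                                min_overlap = 10))
  expect_error(interval_overlaps(a, a, min_overlap = 0), "min_overlap")

  subj <- genomic_intervals(c("chr1", "chr1"), c(0, 500), c(50, 600))
  q <- genomic_intervals(c("chr1", "chr1", "chr3"), c(40, 50, 0),
                         c(60, 500, 100))
  expect_equal(overlap_any(q, subj), c(TRUE, FALSE, FALSE))
})

test_that("coverage_from_fragments bins per-base depth means", {
  cs <- c(chrA = 1000)
  # one fragment exactly covering bin 2
  tr <- coverage_from_fragments(genomic_intervals("chrA", 100, 200), 100, cs)
  expect_equal(tr$values$chrA, c(0, 1, rep(0, 8)))
  expect_equal(tr$total_mapped, 1)
  # additivity: two identical fragments
  tr2 <- coverage_from_fragments(
    genomic_intervals(rep("chrA", 2), c(100, 100), c(200, 200)), 100, cs)
  expect_equal(tr2$values$chrA[2], 2)
  # 50 bp fragment in a 100 bp bin -> 0.5 mean depth
  tr3 <- coverage_from_fragments(genomic_intervals("chrA", 100, 150), 100, cs)
  expect_equal(tr3$values$chrA[2], 0.5)
  expect_error(coverage_from_fragments(genomic_intervals("chrZ", 0, 10), 100, cs),
               "unknown chromosome")
})

test_that("coverage is additive over fragment lists (property)", {
  withr::with_seed(7, {
    cs <- c(chrA = 5000, chrB = 3000)
    mk <- function(n) {
      chrom <- sample(names(cs), n, replace = TRUE)
      start <- floor(runif(n, 0, cs[chrom] - 200))
      genomic_intervals(chrom, start, start + sample(50:200, n, TRUE))
    }
    f1 <- mk(40); f2 <- mk(25)
    cov_union <- coverage_from_fragments(bind_intervals_for_test(f1, f2), 100, cs)
    cov_sum <- Map(`+`, coverage_from_fragments(f1, 100, cs)$values,
                   coverage_from_fragments(f2, 100, cs)$values)
    expect_equal(cov_union$values, cov_sum)
  })
})

test_that("rpkm_normalize applies the closed-form factor and is linear", {
  cs <- c(chrA = 300)
  tr <- coverage_track(list(chrA = c(1, 0, 2)), 100, cs,
                       total_mapped = 1e6)
  r <- rpkm_normalize(tr)
  expect_equal(r$values$chrA, c(10, 0, 20))   # v * (1000/100) * (1e6/1e6)
  expect_equal(r$normalization, "RPKM")
  expect_error(rpkm_normalize(r), "already normalized")
  # doubling total_mapped halves every value
  tr2 <- tr; tr2$total_mapped <- 2e6
  expect_equal(rpkm_normalize(tr2)$values$chrA, c(5, 0, 10))
  # linearity in the values for fixed total_mapped
  tr3 <- tr; tr3$values$chrA <- 3 * tr$values$chrA
  expect_equal(rpkm_normalize(tr3)$values$chrA, 3 * r$values$chrA)
  tr0 <- coverage_track(list(chrA = numeric(3)), 100, cs, total_mapped = 10)
  expect_equal(rpkm_normalize(tr0)$values$chrA, numeric(3))
})

test_that("mean_signal is a length-weighted bin mean", {
  cs <- c(chrA = 400)
  tr <- coverage_track(list(chrA = c(2, 4, 7, 0)), 100, cs)
  # spans bins 1 and 2 equally
  expect_equal(mean_signal(tr, genomic_intervals("chrA", 50, 150)), 3)
  # fully inside bin 3
  expect_equal(mean_signal(tr, genomic_intervals("chrA", 210, 260)), 7)
  # 3:1 weighting of bins 1 and 2
  expect_equal(mean_signal(tr, genomic_intervals("chrA", 25, 125)),
               (2 * 75 + 4 * 25) / 100)
  expect_error(mean_signal(tr, data.frame(chrom = "chrA", start = 50, end = 50)),
               "interval")
  expect_error(mean_signal(tr, genomic_intervals("chrZ", 0, 10)), "absent")
})

test_that("mean_signal of a constant track equals the constant (property)", {
  withr::with_seed(11, {
    cs <- c(chrA = 1730)  # deliberately not a bin multiple
    tr <- coverage_track(list(chrA = rep(3.25, ceiling(1730 / 100))), 100, cs)
    for (k in 1:25) {
      s <- floor(runif(1, 0, 1729)); e <- s + sample(1:(1730 - s), 1)
      expect_equal(mean_signal(tr, data.frame(chrom = "chrA", start = s, end = e)),
                   3.25)
    }
  })
})

test_that("BedGraph resampling and round trips behave", {
  cs <- c(chrA = 300)
  # one record exactly covering a bin
  f <- tmpfile("chrA\t100\t200\t7")
  expect_equal(read_bedgraph(f, 100, cs)$values$chrA, c(0, 7, 0))
  # 50 bp record of value 4 inside a bin -> length-weighted mean 2
  f2 <- tmpfile("chrA\t100\t150\t4")
  expect_equal(read_bedgraph(f2, 100, cs)$values$chrA, c(0, 2, 0))
  expect_error(read_bedgraph(tmpfile(c("chrA\t0\t100\t1", "chrA\t50\t150\t1")),
                             100, cs), "overlapping")
  # constant-track round trip
  tr <- coverage_track(list(chrA = rep(5.5, 3)), 100, cs)
  f3 <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f3)
  expect_equal(read_bedgraph(f3, 100, cs)$values, tr$values)
  # run-length merge: constant track writes a single record
  expect_equal(length(readLines(f3)), 1L)
})

test_that("chrom sizes TSV round trips", {
  f <- tmpfile(c("chr2L\t23513712", "chr3R\t32079331"))
  cs <- read_chrom_sizes(f)
  expect_equal(cs, c(chr2L = 23513712, chr3R = 32079331))
})
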