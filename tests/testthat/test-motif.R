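test_that("load_pwm derives log-odds per the count/pseudocount formula", {
  f <- tmpfile(c("A\tC\tG\tT", "10\t0\t0\t0"))
  p <- load_pwm(f)  # uniform background, pseudocount 1
  expect_equal(unname(p$log_odds[1, "A"]), log2((10.25 / 11) / 0.25))
  expect_equal(unname(p$log_odds[1, "C"]), log2((0.25 / 11) / 0.25))
  expect_equal(p$max_score, log2((10.25 / 11) / 0.25))

  # equal counts + uniform background: log-odds shrink to 0 as pseudocount grows
  f2 <- tmpfile(c("5 5 5 5", "5 5 5 5"))
  p_small <- load_pwm(f2, pseudocount = 1)
  p_big <- load_pwm(f2, pseudocount = 1e6)
  expect_equal(p_small$log_odds, p_small$log_odds * 0 ,
               tolerance = 1e-12)  # already uniform: exactly 0
  expect_lt(max(abs(p_big$log_odds)), 1e-6)

  expect_error(load_pwm(tmpfile("1 2 3")), "4 columns")
  expect_error(load_pwm(tmpfile(c("1 2 3 4", "1 2 3"))), "rectangular")
  expect_error(pwm(matrix(c(-1, 1, 1, 1), 1)), "non-negative")
  # transposed 4-row layout accepted
  p4 <- load_pwm(tmpfile(c("9 0", "0 9", "0 0", "1 1")))
  expect_equal(p4$length, 2)
  expect_equal(unname(consensus_word(p4)), c(1L, 2L))
})

test_that("score_threshold honors the limit cases", {
  p <- pwm(rbind(c(10, 0, 0, 0), c(0, 10, 0, 0), c(0, 0, 10, 0)))
  expect_equal(as.numeric(score_threshold(p, 1)), p$min_score)
  # p below the probability of the unique best word -> max attainable score
  expect_equal(as.numeric(score_threshold(p, 4^-3 / 2)), p$max_score)
})

test_that("DP threshold matches exhaustive enumeration at grid resolution", {
  withr::with_seed(101, {
    eps <- 1e-3
    for (rep in 1:12) {
      L <- sample(3:6, 1)
      p <- pwm(random_pwm_counts(L))
      oracle <- exhaustive_pwm_tail(p)
      for (pv in c(1e-2, 1e-3, 1e-4)) {
        thr <- score_threshold(p, pv, granularity = eps)
        t_star <- oracle$threshold(pv)
        if (!is.finite(t_star)) {
          expect_equal(as.numeric(thr), p$max_score)
          next
        }
        # conservative: exact tail at DP threshold never exceeds requested p
        expect_lte(oracle$tail_at(as.numeric(thr)), pv + 1e-12)
        # and not more conservative than the grid can explain
        expect_lte(as.numeric(thr), t_star + (L + 1) * eps)
      }
    }
  })
})

test_that("score_threshold is non-increasing in p and achieved_p <= requested", {
  withr::with_seed(5, {
    p <- pwm(random_pwm_counts(8))
    ps <- c(1e-5, 1e-4, 1e-3, 1e-2, 0.1, 0.5, 1)
    thr <- vapply(ps, function(pp) as.numeric(score_threshold(p, pp)), 0)
    expect_true(all(diff(thr) <= 1e-12))
    # achieved tail <= requested wherever the requested p is attainable at
    # all (p >= 4^-L, the probability mass of a single background word)
    for (pp in ps[ps >= 4^-8]) {
      expect_lte(attr(score_threshold(p, pp), "achieved_p"), pp)
    }
  })
  expect_error(score_threshold(pwm(random_pwm_counts(3)), 0), "p_value")
})

test_that("scan_pwm finds planted words on both strands in forward coords", {
  p <- pita_pwm()
  word <- paste(c("A", "C", "G", "T")[consensus_word(p)], collapse = "")
  thr <- score_threshold(p, 1e-4)
  left <- "GGGGGGGGGG"; right <- "CCCCCCCCCCCCCCC"
  seqf <- paste0(left, word, right)
  h <- scan_pwm(seqf, p, thr)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, nchar(left))
  expect_equal(h$end, nchar(left) + p$length)
  expect_equal(h$strand, "+")
  expect_equal(h$score, p$max_score)

  # reverse complement of the whole sequence: one minus-strand hit at the
  # reflected coordinate
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seqf, "")[[1]]), collapse = ""))
  h2 <- scan_pwm(rc, p, thr)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, nchar(right))
  expect_equal(h2$score, p$max_score)

  # N in the window kills the hit; shorter-than-motif input is empty
  seqn <- paste0(left, sub("^.", "N", word), right)
  expect_equal(nrow(scan_pwm(seqn, p, thr)), 0)
  expect_equal(nrow(scan_pwm("ACGT", p, thr)), 0)
})

test_that("strand symmetry: forward scan equals reflected reverse scan (property)", {
  withr::with_seed(23, {
    p <- pwm(random_pwm_counts(5))
    thr <- as.numeric(score_threshold(p, 0.05))
    for (k in 1:5) {
      s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
      rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
      fwd <- scan_pwm(s, p, thr, strands = "+")
      rev_on_rc <- scan_pwm(rc, p, thr, strands = "-")
      # reflect reverse-strand hits on rc back into s coordinates
      expect_equal(sort(fwd$start), sort(300 - rev_on_rc$end))
      expect_equal(sort(fwd$score), sort(rev_on_rc$score))
    }
  })
})

test_that("background hit rate at the 1e-4 threshold is Poisson-consistent", {
  withr::with_seed(31, {
    p <- pita_pwm()
    thr <- score_threshold(p, 1e-4)
    ach <- attr(thr, "achieved_p")
    n <- 1e5
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    hits <- nrow(scan_pwm(s, p, thr))
    lam <- 2 * (n - p$length + 1) * ach
    expect_lte(hits, qpois(0.9995, lam))
  })
})

test_that("annotate_motif_peaks flags planted motifs and honors search_flank", {
  p <- pita_pwm()
  word <- paste(c("A", "C", "G", "T")[consensus_word(p)], collapse = "")
  base <- strrep("G", 3000)
  plant_at <- function(pos) {  # 0-based
    paste0(substr(base, 1, pos), word, substr(base, pos + 16, 3000))
  }
  pk <- peaks("chrA", 1300, 1700, 200, 10, 1e-6)  # summit 1500, window 1250..1750

  genome <- c(chrA = plant_at(1493))               # at the summit
  expect_true(annotate_motif_peaks(pk, genome, p))
  # poly-G background only: no hit
  expect_false(annotate_motif_peaks(pk, c(chrA = base), p))
  # motif at 2050..2065: 300 bp beyond the window end (1750)
  g2 <- c(chrA = plant_at(2050))
  expect_false(annotate_motif_peaks(pk, g2, p, search_flank = 0))
  expect_true(annotate_motif_peaks(pk, g2, p, search_flank = 350))
  expect_error(annotate_motif_peaks(pk, c(chrB = base), p), "absent")
})
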