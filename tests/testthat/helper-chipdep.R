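# shared fixtures and independent oracles, all built in code

# desk-scale scenario for unit tests (small genome, light depth)
small_scenario <- function(...) {
  args <- list(chrom_sizes = c(chrT1 = 3e5, chrT2 = 2e5), n_peaks = 20,
               read_depth = 3e4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(chip_scenario, args)
}

tmpfile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# random PWM count matrix of length L (counts out of `depth` observations)
random_pwm_counts <- function(L, depth = 20) {
  t(vapply(seq_len(L), function(i) {
    as.numeric(rmultinom(1, depth, runif(4)))
  }, numeric(4)))
}

# exhaustive-enumeration oracle for PWM score thresholds: scores all 4^L
# words, returns the smallest achievable score whose exact background tail
# probability is <= p, plus a function giving the exact tail at any score
exhaustive_pwm_tail <- function(pw) {
  L <- pw$length
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- numeric(nrow(words))
  pr <- rep(1, nrow(words))
  for (i in seq_len(L)) {
    sc <- sc + pw$log_odds[i, ][words[, i]]
    pr <- pr * pw$background[words[, i]]
  }
  # aggregate tied word scores so a tail never splits a tied block
  key <- round(sc, 9)
  agg <- rowsum(pr, key)
  usc <- sort(unique(key), decreasing = TRUE)
  upr <- agg[as.character(usc), 1]
  ctail <- cumsum(upr)
  list(
    threshold = function(p) {
      # smallest achievable score t with P(score >= t) <= p
      ok <- which(ctail <= p + 1e-12)
      if (!length(ok)) return(Inf)
      usc[max(ok)]
    },
    tail_at = function(t) sum(upr[usc >= t - 1e-9]),
    scores = usc, probs = upr
  )
}

bind_intervals_for_test <- function(...) chipdep:::bind_intervals(...)

# membership-in-truth matching by nearest planted center
nearest_center_error <- function(pk, truth) {
  vapply(seq_len(nrow(pk)), function(i) {
    j <- which(truth$chrom == pk$chrom[i])
    if (!length(j)) return(Inf)
    min(abs(truth$center[j] - summit_pos(pk[i, ])))
  }, numeric(1))
}
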