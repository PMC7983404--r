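#' One-sided upper Grubbs statistic
#'
#' `G = (max(values) - mean(values)) / sd(values)` with the
#' N-1-denominator sample standard deviation; the candidate outlier is
#' the (leftmost) maximum.
#'
#' @param values numeric vector, length >= 3, non-constant
#' @return list with `G` and `index` of the maximum
#' @export
grubbs_upper <- function(values) {
  n <- length(values)
  if (n < 3) stop("grubbs_upper: need at least 3 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("grubbs_upper: zero standard deviation, sample untestable")
  }
  i <- which.max(values)
  list(G = (values[i] - mean(values)) / s, index = i)
}

#' P-value of the one-sided upper Grubbs test
#'
#' Inverts the standard single-outlier critical-value relation
#' `G_crit(alpha, N) = ((N-1)/sqrt(N)) * sqrt(t^2 / (N-2+t^2))`, with
#' `t` the upper `alpha/N` quantile of the t distribution on `N-2`
#' degrees of freedom, so that `grubbs_p_value(G, N) < alpha` exactly
#' when `G > G_crit(alpha, N)`. The result is clipped to \[0, 1\].
#'
#' @param G Grubbs statistic
#' @param N sample size (>= 3)
#' @return p-value
#' @export
grubbs_p_value <- function(G, N) {
  if (N < 3) stop("grubbs_p_value: need N >= 3")
  if (G <= 0) return(1)
  g <- G * sqrt(N) / (N - 1)
  if (g >= 1) return(0)
  t <- sqrt((N - 2) * g^2 / (1 - g^2))
  p <- N * stats::pt(t, df = N - 2, lower.tail = FALSE)
  min(1, max(0, p))
}

#' Critical value of the one-sided upper Grubbs test
#' @param alpha significance level
#' @param N sample size (>= 3)
#' @return critical G value
#' @export
grubbs_critical <- function(alpha, N) {
  if (N < 3) stop("grubbs_critical: need N >= 3")
  t <- stats::qt(alpha / N, df = N - 2, lower.tail = FALSE)
  (N - 1) / sqrt(N) * sqrt(t^2 / (N - 2 + t^2))
}

#' Iterative upper-outlier detection
#'
#' Repeatedly applies the one-sided upper Grubbs test to the remaining
#' values, removing the detected maximum while its p-value stays below
#' `alpha`. The first non-significant iteration terminates the
#' procedure and is not recorded; removed values never re-enter.
#' Iteration also stops cleanly when fewer than 3 values remain or the
#' remainder is constant. The detected index set is invariant under
#' positive affine transforms of the input.
#'
#' @param values numeric vector (length >= 3 to test at all)
#' @param alpha per-iteration significance level (default 0.05)
#' @param max_iter cap on detected outliers
#' @return a `grubbs_result`: `outlier_indices` (original positions,
#'   detection order), per-iteration `statistics` and `p_values`, and
#'   `alpha`
#' @export
iterative_grubbs <- function(values, alpha = 0.05, max_iter = length(values)) {
  idx <- seq_along(values)
  out_i <- integer(0); out_G <- numeric(0); out_p <- numeric(0)
  remaining <- values
  while (length(remaining) >= 3 && length(out_i) < max_iter) {
    rng <- range(remaining)
    # effectively-constant samples (incl. floating-point noise) are untestable
    if (rng[2] - rng[1] <= 1e-9 * max(1, abs(rng[1]), abs(rng[2]))) break
    g <- grubbs_upper(remaining)
    p <- grubbs_p_value(g$G, length(remaining))
    if (!(p < alpha)) break
    out_i <- c(out_i, idx[g$index])
    out_G <- c(out_G, g$G)
    out_p <- c(out_p, p)
    remaining <- remaining[-g$index]
    idx <- idx[-g$index]
  }
  structure(list(outlier_indices = out_i, statistics = out_G,
                 p_values = out_p, alpha = alpha),
            class = "grubbs_result")
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("<grubbs_result> %d upper outlier(s) at alpha = %g\n",
              length(x$outlier_indices), x$alpha))
  invisible(x)
}
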