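#' Position weight matrices
#'
#' A PWM is stored as per-position nucleotide counts plus a background
#' model; log-odds scores (bits) are derived as
#' `log2(((counts + pseudocount * background) / (rowsum + pseudocount)) / background)`.
#' Score thresholds are set by an exact tail probability under the
#' background model (see [score_threshold()]), the standard
#' SARUS/MACRO-style "p-value threshold" semantics.
#'
#' @param counts L x 4 numeric matrix of nucleotide counts, columns
#'   A, C, G, T
#' @param background nucleotide background frequencies summing to 1
#'   (default uniform)
#' @param pseudocount Laplace-style regularizer distributed by
#'   background (> 0, default 1)
#' @return object of class `pwm`
#' @export
pwm <- function(counts, background = rep(0.25, 4), pseudocount = 1) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) stop("pwm: counts must have 4 columns (A, C, G, T)")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("pwm: counts must be finite and non-negative")
  }
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    stop("pwm: background must be 4 positive frequencies summing to 1")
  }
  if (pseudocount <= 0) stop("pwm: pseudocount must be > 0")
  colnames(counts) <- c("A", "C", "G", "T")
  p <- (counts + pseudocount * rep(background, each = nrow(counts))) /
    (rowSums(counts) + pseudocount)
  lo <- log2(sweep(p, 2, background, "/"))
  structure(list(length = nrow(counts), counts = counts,
                 background = background, pseudocount = pseudocount,
                 log_odds = lo,
                 max_score = sum(apply(lo, 1, max)),
                 min_score = sum(apply(lo, 1, min))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %d positions, score range [%.3f, %.3f] bits, consensus %s\n",
              x$length, x$min_score, x$max_score,
              paste(c("A", "C", "G", "T")[consensus_word(x)], collapse = "")))
  invisible(x)
}

#' Maximum-scoring word of a PWM
#' @param x a `pwm`
#' @return integer vector (1=A, 2=C, 3=G, 4=T), leftmost column on ties
#' @export
consensus_word <- function(x) apply(x$log_odds, 1, which.max)

#' Load a PWM count matrix from a text file
#'
#' Accepts a whitespace-separated numeric matrix with one row per
#' motif position and columns A C G T (an optional `A C G T` header
#' and a leading position column are tolerated), or the transposed
#' 4-row layout.
#'
#' @param path matrix file
#' @inheritParams pwm
#' @return a `pwm`
#' @export
load_pwm <- function(path, background = rep(0.25, 4), pseudocount = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[#>]", lines)]
  tok <- strsplit(trimws(lines), "[ \t]+")
  if (length(tok) && all(toupper(tok[[1]]) %in% c("A", "C", "G", "T", "POS", "PO"))) {
    tok <- tok[-1]
  }
  num <- suppressWarnings(lapply(tok, as.numeric))
  # drop a non-numeric leading label column if present
  num <- lapply(num, function(v) if (length(v) && is.na(v[1])) v[-1] else v)
  if (!length(num) || length(unique(lengths(num))) != 1 ||
      any(vapply(num, anyNA, TRUE))) {
    stop("load_pwm: ", path, " is not a rectangular numeric matrix")
  }
  m <- do.call(rbind, num)
  if (ncol(m) != 4) {
    if (nrow(m) == 4) m <- t(m)
    else stop("load_pwm: ", path, " must have 4 columns (A, C, G, T); got ",
              ncol(m))
  }
  pwm(m, background = background, pseudocount = pseudocount)
}

#' Bundled synthetic 15-bp motif matrix
#'
#' A synthetic stand-in for the zinc-finger protein's 15-bp consensus
#' binding-site PWM (the real matrix ships with the original study's
#' supplementary data and is not redistributed here). Constructed once
#' with a fixed seed; stored as a plain-text count matrix under
#' `inst/extdata/pita_pwm_synthetic.txt`.
#'
#' @inheritParams pwm
#' @return a `pwm`
#' @export
pita_pwm <- function(background = rep(0.25, 4), pseudocount = 1) {
  path <- system.file("extdata", "pita_pwm_synthetic.txt", package = "chipdep",
                      mustWork = TRUE)
  load_pwm(path, background = background, pseudocount = pseudocount)
}

# ---- exact score-threshold machinery -------------------------------------

#' Score threshold for a requested tail p-value
#'
#' Computes the score distribution of a random background word by
#' dynamic programming over a discretized score grid (granularity
#' `granularity` bits, scores rounded down while building the
#' distribution and the threshold rounded up), and returns the smallest
#' threshold `t` whose achieved tail probability
#' `P(score >= t)` is guaranteed `<= p_value`. The returned value
#' carries the DP's achieved tail probability as attribute
#' `achieved_p`.
#'
#' @param x a `pwm`
#' @param p_value requested tail probability in (0, 1]
#' @param granularity score grid step in bits (default 1e-3)
#' @return threshold score (bits), never above the maximum attainable
#'   score
#' @export
score_threshold <- function(x, p_value, granularity = 1e-3) {
  stopifnot(inherits(x, "pwm"))
  if (!is.numeric(p_value) || length(p_value) != 1 ||
      p_value <= 0 || p_value > 1) {
    stop("score_threshold: p_value must be in (0, 1]")
  }
  if (p_value == 1) {
    return(structure(x$min_score, achieved_p = 1))
  }
  q <- matrix(as.integer(floor(x$log_odds / granularity)), nrow = x$length)
  offs <- apply(q, 1, min)
  span <- apply(q, 1, max) - offs
  dist <- 1
  for (i in seq_len(x$length)) {
    new <- numeric(length(dist) + span[i])
    for (b in 1:4) {
      sh <- q[i, b] - offs[i]
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * x$background[b]
    }
    dist <- new
  }
  tail <- rev(cumsum(rev(dist)))
  k <- which(tail <= p_value)
  if (!length(k)) {
    thr <- x$max_score
    ach <- tail[length(tail)]
  } else {
    k <- k[1]
    ach <- tail[k]
    # grid score of slot k, plus one grid step per position of
    # round-down slack, keeps the threshold conservative for true scores
    thr <- (k - 1 + sum(offs)) * granularity + x$length * granularity
    thr <- min(thr, x$max_score)
  }
  structure(thr, achieved_p = ach)
}

# ---- scanning -------------------------------------------------------------

BASE_LOOKUP <- local({
  v <- rep(NA_integer_, 127)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("a")] <- 1L
  v[utf8ToInt("C")] <- 2L; v[utf8ToInt("c")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("g")] <- 3L
  v[utf8ToInt("T")] <- 4L; v[utf8ToInt("t")] <- 4L
  v
})

seq_to_int <- function(sequence) BASE_LOOKUP[utf8ToInt(sequence)]

window_scores <- function(xi, lo) {
  L <- nrow(lo)
  n <- length(xi) - L + 1
  if (n < 1) return(numeric(0))
  bad <- is.na(xi)
  xi[bad] <- 1L
  sc <- numeric(n)
  for (i in seq_len(L)) sc <- sc + lo[i, ][xi[i:(i + n - 1)]]
  if (any(bad)) {
    cb <- cumsum(bad)
    nbad <- cb[L:length(xi)] - c(0, cb)[seq_len(n)]
    sc[nbad > 0] <- -Inf
  }
  sc
}

#' Scan a sequence for PWM hits
#'
#' Reports every window of length `pwm$length` scoring at least
#' `threshold` on the requested strand(s). Reverse-strand windows are
#' scored on the reverse complement and reported in forward
#' coordinates; windows containing non-ACGT characters are skipped.
#'
#' @param sequence a character scalar over A/C/G/T/N
#' @param x a `pwm`
#' @param threshold minimum reported score (from [score_threshold()])
#' @param strands `"both"`, `"+"` or `"-"`
#' @param chrom chromosome label attached to hits
#' @param offset 0-based coordinate of the first sequence character
#' @return data frame of hits: `chrom`, `start`, `end` (half-open
#'   forward coordinates), `strand`, `score`
#' @export
scan_pwm <- function(sequence, x, threshold, strands = c("both", "+", "-"),
                     chrom = "seq", offset = 0) {
  stopifnot(inherits(x, "pwm"))
  strands <- match.arg(strands)
  L <- x$length
  xi <- seq_to_int(sequence)
  hits <- list()
  if (strands %in% c("both", "+")) {
    sc <- window_scores(xi, x$log_odds)
    j <- which(sc >= threshold)
    if (length(j)) {
      hits[["+"]] <- data.frame(chrom = chrom, start = offset + j - 1,
                                end = offset + j - 1 + L, strand = "+",
                                score = sc[j], stringsAsFactors = FALSE)
    }
  }
  if (strands %in% c("both", "-")) {
    rc <- rev(5L - xi)  # A<->T, C<->G on the 1..4 encoding; NA stays NA
    sc <- window_scores(rc, x$log_odds)
    j <- which(sc >= threshold)
    if (length(j)) {
      n <- length(xi)
      fstart <- offset + n - (j - 1) - L
      hits[["-"]] <- data.frame(chrom = chrom, start = fstart,
                                end = fstart + L, strand = "-",
                                score = sc[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Flag peaks by motif presence near their summit window
#'
#' Scans `[window_start - search_flank, window_end + search_flank)`
#' around each standardized summit window on both strands and flags the
#' peak when at least one hit at the exact `p_value` score threshold
#' overlaps that region. This is the motif partition that splits the
#' analysis universe into motif and non-motif site classes.
#'
#' @param pk peak data frame
#' @param genome named character vector of chromosome sequences
#' @param x a `pwm`
#' @param p_value motif tail p-value (default 1e-4)
#' @param flank summit-window half-width (default 250)
#' @param search_flank extra search margin beyond the window (default
#'   250, i.e. summit +/- 500 in total)
#' @return logical vector, one flag per peak
#' @export
annotate_motif_peaks <- function(pk, genome, x, p_value = 1e-4,
                                 flank = 250, search_flank = 250) {
  missing_chr <- setdiff(unique(pk$chrom), names(genome))
  if (length(missing_chr)) {
    stop("annotate_motif_peaks: chromosome ", missing_chr[1],
         " absent from genome")
  }
  thr <- score_threshold(x, p_value)
  sizes <- nchar(genome)
  win <- summit_window(pk, flank = flank,
                       chrom_sizes = stats::setNames(sizes, names(genome)))
  rs <- pmax(0, win$start - search_flank)
  re <- pmin(sizes[pk$chrom], win$end + search_flank)
  # extend extraction so hits straddling the region edge are seen
  xs <- pmax(0, rs - (x$length - 1))
  xe <- pmin(sizes[pk$chrom], re + (x$length - 1))
  out <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    s <- substr(genome[[pk$chrom[i]]], xs[i] + 1, xe[i])
    h <- scan_pwm(s, x, thr, chrom = pk$chrom[i], offset = xs[i])
    out[i] <- any(h$end > rs[i] & h$start < re[i])
  }
  out
}
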