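#' Call enriched peaks against a control library
#'
#' A deliberately simplified MACS-style caller operating on a fixed
#' 100 bp bin grid: per bin, the treatment fragment-midpoint count is
#' tested against a Poisson upper tail whose rate is the most
#' conservative of the genome-wide, 5 kb and 10 kb local estimates from
#' the depth-scaled control (`lambda_local = max(lambda_genome,
#' lambda_5k, lambda_10k)`). Bins with `p <= p_threshold` are merged
#' when closer than one fragment length; the summit is the bin of
#' maximum treatment count within the merged region (leftmost on ties)
#' and each peak carries its minimum bin p-value.
#'
#' @param treatment,control fragment interval data frames (both
#'   non-empty)
#' @param p_threshold per-bin Poisson p-value cutoff (default 1e-2)
#' @param chrom_sizes named vector of chromosome lengths
#' @param bin_width bin width in bp (default 100)
#' @param merge_gap gap (bp) within which significant bins are merged;
#'   defaults to the median treatment fragment length
#' @return peak data frame sorted by position
#' @export
call_peaks <- function(treatment, control, p_threshold = 1e-2, chrom_sizes,
                       bin_width = 100, merge_gap = NULL) {
  if (!nrow(treatment)) stop("call_peaks: empty treatment fragment set")
  if (!nrow(control)) stop("call_peaks: empty control fragment set")
  if (is.null(merge_gap)) {
    merge_gap <- stats::median(treatment$end - treatment$start)
  }
  gap_bins <- max(1L, as.integer(ceiling(merge_gap / bin_width)))
  bins <- peak_bin_pvalues(treatment, control, chrom_sizes, bin_width)
  res <- list()
  for (chr in names(chrom_sizes)) {
    L <- as.numeric(chrom_sizes[[chr]])
    tc <- bins[[chr]]$count
    p <- bins[[chr]]$p_value
    sig <- which(p <= p_threshold)
    if (!length(sig)) next
    grp <- cumsum(c(1L, diff(sig) > gap_bins))
    first <- sig[!duplicated(grp)]
    last <- sig[!duplicated(grp, fromLast = TRUE)]
    n <- length(first)
    start <- (first - 1) * bin_width
    end <- pmin(L, last * bin_width)
    summit <- numeric(n); pmin_v <- numeric(n)
    for (g in seq_len(n)) {
      rbins <- first[g]:last[g]
      b <- rbins[which.max(tc[rbins])]
      summit[g] <- min((b - 1) * bin_width + bin_width / 2, L - 1)
      pmin_v[g] <- min(p[rbins])
    }
    res[[chr]] <- data.frame(chrom = chr, start = start, end = end,
                             summit_offset = summit - start,
                             score = -log10(pmax(pmin_v, 1e-300)),
                             p_value = pmin_v, stringsAsFactors = FALSE)
  }
  if (!length(res)) return(peaks())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  validate_peaks(out, "called peaks")
  out
}

#' Per-bin Poisson enrichment p-values
#'
#' The bin-level statistic underlying [call_peaks()]: treatment
#' fragment-midpoint counts per fixed-width bin, tested against the
#' most conservative of the genome-wide, 5 kb and 10 kb local Poisson
#' rates estimated from the depth-scaled control.
#'
#' @inheritParams call_peaks
#' @return named list (per chromosome) of data frames with `count`,
#'   `lambda`, `p_value` per bin
#' @export
peak_bin_pvalues <- function(treatment, control, chrom_sizes, bin_width = 100) {
  if (!nrow(treatment)) stop("empty treatment fragment set")
  if (!nrow(control)) stop("empty control fragment set")
  unknown <- setdiff(unique(treatment$chrom), names(chrom_sizes))
  if (length(unknown)) stop("fragment on unknown chromosome ", unknown[1])
  scale <- nrow(treatment) / nrow(control)
  nb_all <- ceiling(as.numeric(chrom_sizes) / bin_width)
  lambda_genome <- scale * nrow(control) / sum(nb_all)
  out <- vector("list", length(chrom_sizes))
  names(out) <- names(chrom_sizes)
  for (chr in names(chrom_sizes)) {
    nb <- as.integer(ceiling(chrom_sizes[[chr]] / bin_width))
    ti <- treatment$chrom == chr
    ci <- control$chrom == chr
    tmid <- floor((treatment$start[ti] + treatment$end[ti]) / 2)
    cmid <- floor((control$start[ci] + control$end[ci]) / 2)
    tc <- tabulate(pmin(nb, floor(tmid / bin_width) + 1L), nb)
    cc <- tabulate(pmin(nb, floor(cmid / bin_width) + 1L), nb)
    lam5 <- scale * running_mean(cc, max(1L, as.integer(5000 / bin_width)))
    lam10 <- scale * running_mean(cc, max(1L, as.integer(10000 / bin_width)))
    lam <- pmax(lambda_genome, lam5, lam10)
    out[[chr]] <- data.frame(count = tc, lambda = lam,
                             p_value = stats::ppois(tc - 1, lam,
                                                    lower.tail = FALSE))
  }
  out
}

# centered running mean with clipped (partial) edge windows
running_mean <- function(x, halfspan_bins) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - halfspan_bins %/% 2L)
  hi <- pmin(n, seq_len(n) + halfspan_bins %/% 2L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Remove peaks overlapping blacklist regions
#'
#' Discards peaks with >= 1 bp overlap with any blacklist interval;
#' order is preserved and the operation is idempotent.
#'
#' @param pk peak data frame
#' @param blacklist interval data frame (possibly empty)
#' @return filtered peak data frame
#' @export
filter_blacklist <- function(pk, blacklist) {
  if (is.null(blacklist) || !nrow(blacklist) || !nrow(pk)) return(pk)
  keep <- !overlap_any(pk, blacklist)
  out <- pk[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate-reproduced peak set
#'
#' Keeps the pooled-library peaks whose standardized summit windows
#' overlap (>= 1 bp) a peak window in replicate 1 AND one in
#' replicate 2 — the overlap-based stand-in for an IDR concordance
#' filter. The pooled peak (and its summit) is what survives.
#'
#' @param rep1,rep2,pooled peak data frames from the same sample
#' @param flank summit-window half-width used for the overlap test
#' @param chrom_sizes chromosome lengths for window clipping
#' @return subset of `pooled`
#' @export
reproduced_peak_set <- function(rep1, rep2, pooled, flank = 250,
                                chrom_sizes = NULL) {
  if (!nrow(pooled) || !nrow(rep1) || !nrow(rep2)) return(peaks())
  wp <- summit_window(pooled, flank, chrom_sizes)
  keep <- overlap_any(wp, summit_window(rep1, flank, chrom_sizes)) &
    overlap_any(wp, summit_window(rep2, flank, chrom_sizes))
  out <- pooled[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-genotype analysis universe
#'
#' Union of the two genotypes' reproduced peak sets, with peaks whose
#' summit windows overlap merged into one record that keeps the summit
#' (and coordinates) of the stronger peak (higher score; leftmost on
#' ties). This union is the universe over which all signal tables and
#' group partitions are computed.
#'
#' @param peaks_wt,peaks_mut reproduced peak sets
#' @param flank summit-window half-width
#' @param chrom_sizes chromosome lengths for window clipping
#' @return merged peak data frame sorted by position
#' @export
cross_genotype_peak_set <- function(peaks_wt, peaks_mut, flank = 250,
                                    chrom_sizes = NULL) {
  all <- bind_intervals(peaks_wt, peaks_mut)
  if (!nrow(all)) return(peaks())
  win <- summit_window(all, flank, chrom_sizes)
  keep <- logical(nrow(all))
  for (chr in unique(win$chrom)) {
    i <- which(win$chrom == chr)
    ir <- IRanges::IRanges(as.integer(win$start[i]) + 1L,
                           as.integer(win$end[i]))
    red <- IRanges::reduce(ir)
    cl <- IRanges::findOverlaps(ir, red, select = "first")
    for (g in unique(cl)) {
      j <- i[cl == g]
      best <- j[order(-all$score[j], all$start[j])][1]
      keep[best] <- TRUE
    }
  }
  out <- all[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate reproducibility ratios
#'
#' ENCODE-style pass/fail concordance bookkeeping on peak counts:
#' pooled pseudo-replicates are seeded random halves of the pooled
#' fragment union, self pseudo-replicates are halves of each
#' replicate. The rescue ratio compares the two pooled-pseudo-replicate
#' peak counts, the self-consistency ratio the two replicates'
#' self-consistent peak counts; a sample is acceptable when both
#' ratios are below 2.
#'
#' @param fragments_rep1,fragments_rep2 replicate fragment sets
#' @param control control fragment set for the caller
#' @param chrom_sizes chromosome lengths
#' @param p_threshold caller p-value threshold
#' @param flank summit-window half-width for reproduced-overlap counts
#' @param seed seed for the pseudo-replicate splits
#' @return a `reproducibility_report` list with peak counts, both
#'   ratios (>= 1 by construction) and the `acceptable` flag
#' @export
consistency_ratios <- function(fragments_rep1, fragments_rep2, control,
                               chrom_sizes, p_threshold = 1e-2, flank = 250,
                               seed = 1L) {
  if (!nrow(fragments_rep1) || !nrow(fragments_rep2)) {
    stop("consistency_ratios: empty replicate fragment set")
  }
  halves <- function(fr) {
    n <- nrow(fr)
    i <- sample.int(n, floor(n / 2))
    if (!length(i) || length(i) == n) {
      stop("consistency_ratios: pseudo-replicate with zero fragments")
    }
    list(fr[i, , drop = FALSE], fr[-i, , drop = FALSE])
  }
  cp <- function(fr) call_peaks(fr, control, p_threshold, chrom_sizes)
  withr::with_seed(seed, {
    pooled <- bind_intervals(fragments_rep1, fragments_rep2)
    pr <- halves(pooled)
    s1 <- halves(fragments_rep1)
    s2 <- halves(fragments_rep2)
    pk_r1 <- cp(fragments_rep1); pk_r2 <- cp(fragments_rep2)
    pk_pooled <- cp(pooled)
    pk_pr1 <- cp(pr[[1]]); pk_pr2 <- cp(pr[[2]])
    n_pseudo1 <- nrow(reproduced_peak_set(cp(s1[[1]]), cp(s1[[2]]), pk_r1,
                                          flank, chrom_sizes))
    n_pseudo2 <- nrow(reproduced_peak_set(cp(s2[[1]]), cp(s2[[2]]), pk_r2,
                                          flank, chrom_sizes))
  })
  ratio <- function(a, b) {
    if (min(a, b) == 0) return(Inf)
    max(a, b) / min(a, b)
  }
  rr <- ratio(nrow(pk_pr1), nrow(pk_pr2))
  sr <- ratio(n_pseudo1, n_pseudo2)
  structure(list(n_rep1 = nrow(pk_r1), n_rep2 = nrow(pk_r2),
                 n_pooled = nrow(pk_pooled),
                 n_pooled_pr1 = nrow(pk_pr1), n_pooled_pr2 = nrow(pk_pr2),
                 n_pseudo1 = n_pseudo1, n_pseudo2 = n_pseudo2,
                 rescue_ratio = rr, self_consistency_ratio = sr,
                 acceptable = is.finite(rr) && is.finite(sr) && rr < 2 && sr < 2,
                 seed = seed),
            class = "reproducibility_report")
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf(paste0("<reproducibility_report> RR = %.3f, SR = %.3f (%s)\n",
                     "  peaks: rep1 %d, rep2 %d, pooled %d; pooled pseudo %d/%d;",
                     " self-consistent %d/%d\n"),
              x$rescue_ratio, x$self_consistency_ratio,
              if (x$acceptable) "acceptable" else "not acceptable",
              x$n_rep1, x$n_rep2, x$n_pooled, x$n_pooled_pr1, x$n_pooled_pr2,
              x$n_pseudo1, x$n_pseudo2))
  invisible(x)
}
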