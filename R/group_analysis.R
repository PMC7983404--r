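#' Summit-centered signal profile matrix
#'
#' Resamples a coverage track into fixed bins centered on each peak
#' summit (`2 * window_flank / bin_width` bins per row) and orders the
#' rows by a ranking statistic, descending (ties broken by peak
#' position) — the matrix behind ranked signal heatmaps and average
#' profiles. Windows running off a chromosome are zero-padded.
#'
#' @param track a `coverage_track`
#' @param pk peak data frame
#' @param window_flank half-width of the profile window in bp
#'   (default 1000)
#' @param bin_width profile bin width in bp (default 100)
#' @param ranking_values numeric vector aligned with `pk` (default:
#'   mean signal over the profile window)
#' @return a `profile_matrix`: list with `matrix` (rows already
#'   ranked), `bin_width`, `window_flank`, `row_order` (row index into
#'   `pk`), `ranking`
#' @export
profile_matrix <- function(track, pk, window_flank = 1000, bin_width = 100,
                           ranking_values = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  n_bins <- as.integer(2 * window_flank / bin_width)
  if (n_bins < 1 || 2 * window_flank %% bin_width != 0) {
    stop("profile_matrix: 2 * window_flank must be a positive multiple of bin_width")
  }
  s <- summit_pos(pk)
  m <- matrix(0, nrow(pk), n_bins)
  clipped <- FALSE
  for (i in seq_len(nrow(pk))) {
    chr <- pk$chrom[i]
    L <- as.numeric(track$chrom_sizes[[chr]])
    if (is.na(L)) stop("profile_matrix: chromosome ", chr, " absent from track")
    edges <- s[i] - window_flank + (0:n_bins) * bin_width
    for (j in seq_len(n_bins)) {
      a <- edges[j]; b <- edges[j + 1]
      ca <- max(0, a); cb <- min(L, b)
      if (cb <= ca) { clipped <- TRUE; next }
      if (ca > a || cb < b) clipped <- TRUE
      v <- mean_signal(track, data.frame(chrom = chr, start = ca, end = cb))
      m[i, j] <- v * (cb - ca) / bin_width  # off-chromosome part counts as 0
    }
  }
  if (clipped) message("profile_matrix: some windows clipped at chromosome bounds (zero-padded)")
  if (is.null(ranking_values)) ranking_values <- rowMeans(m)
  if (length(ranking_values) != nrow(pk)) {
    stop("profile_matrix: ranking_values must align with peaks")
  }
  o <- order(-ranking_values, pk$chrom, pk$start)
  structure(list(matrix = m[o, , drop = FALSE], bin_width = bin_width,
                 window_flank = window_flank, row_order = o,
                 ranking = ranking_values[o]),
            class = "profile_matrix")
}

#' Column-wise average of a profile matrix
#' @param pm a `profile_matrix` (or plain matrix); must be non-empty
#' @return numeric vector of per-bin means
#' @export
average_profile <- function(pm) {
  m <- if (inherits(pm, "profile_matrix")) pm$matrix else pm
  if (!nrow(m)) stop("average_profile: empty matrix")
  colMeans(m)
}

#' Ranked log-signal curve
#'
#' Orders peaks by the average FLAG signal across the two genotypes
#' (descending) and emits `log10(signal + c)` of the requested signal
#' column along that ranking — the ranked-curve view that exposes
#' per-site cofactor depletion against the binding-strength trend.
#'
#' @param tab a `peak_signal_table`
#' @param signal_column one of `flag_wt`, `flag_mut`, `cp190_wt`,
#'   `cp190_mut`
#' @return data frame `rank`, `peak_id`, `group`, `ranking_signal`,
#'   `log10_signal`
#' @export
ranked_signal_curve <- function(tab, signal_column) {
  cols <- c("flag_wt", "flag_mut", "cp190_wt", "cp190_mut")
  if (!signal_column %in% cols) {
    stop("ranked_signal_curve: unknown signal column ", signal_column)
  }
  c0 <- attr(tab, "pseudocount")
  if (is.null(c0)) c0 <- 0.5
  ranking <- (tab$flag_wt + tab$flag_mut) / 2
  o <- order(-ranking, tab$peak_id)
  data.frame(rank = seq_along(o), peak_id = tab$peak_id[o],
             group = tab$group[o], ranking_signal = ranking[o],
             log10_signal = log10(tab[[signal_column]][o] + c0),
             stringsAsFactors = FALSE)
}

#' Per-group depletion summary
#'
#' For each group: N, mean and median of the four sample signals, and
#' the mean CP190 log2 fold change (wt over mut, same pseudocount as
#' the table). Also reports a two-sided rank-sum (Wilcoxon) test of
#' the CP190 log2 fold changes of GROUP1 versus GROUP2 — the "does
#' cofactor recruitment collapse specifically at depleted sites"
#' contrast. Empty groups are reported as absent (NA statistics).
#'
#' @param tab a partitioned `peak_signal_table`
#' @return list with `per_group` (data frame) and
#'   `cp190_log2fc_group1_vs_group2_p`
#' @export
depletion_summary <- function(tab) {
  if (!all(c("group") %in% names(tab)) || anyNA(tab$group)) {
    stop("depletion_summary: groups not assigned; run partition_groups() first")
  }
  c0 <- attr(tab, "pseudocount")
  if (is.null(c0)) c0 <- 0.5
  cp_lfc <- log2((tab$cp190_wt + c0) / (tab$cp190_mut + c0))
  groups <- c("GROUP1", "GROUP2", "GROUP3")
  rows <- lapply(groups, function(g) {
    i <- which(tab$group == g)
    if (!length(i)) {
      return(data.frame(group = g, n = 0L, flag_wt_mean = NA_real_,
                        flag_mut_mean = NA_real_, cp190_wt_mean = NA_real_,
                        cp190_mut_mean = NA_real_, flag_wt_median = NA_real_,
                        flag_mut_median = NA_real_, cp190_wt_median = NA_real_,
                        cp190_mut_median = NA_real_,
                        cp190_log2fc_mean = NA_real_))
    }
    data.frame(group = g, n = length(i),
               flag_wt_mean = mean(tab$flag_wt[i]),
               flag_mut_mean = mean(tab$flag_mut[i]),
               cp190_wt_mean = mean(tab$cp190_wt[i]),
               cp190_mut_mean = mean(tab$cp190_mut[i]),
               flag_wt_median = stats::median(tab$flag_wt[i]),
               flag_mut_median = stats::median(tab$flag_mut[i]),
               cp190_wt_median = stats::median(tab$cp190_wt[i]),
               cp190_mut_median = stats::median(tab$cp190_mut[i]),
               cp190_log2fc_mean = mean(cp_lfc[i]))
  })
  g1 <- cp_lfc[tab$group == "GROUP1"]
  g2 <- cp_lfc[tab$group == "GROUP2"]
  p <- if (length(g1) && length(g2)) {
    stats::wilcox.test(g1, g2, exact = FALSE)$p.value
  } else {
    NA_real_
  }
  list(per_group = do.call(rbind, rows),
       cp190_log2fc_group1_vs_group2_p = p)
}

#' Co-localization counts with partner peak sets
#'
#' Splits the reference peaks into a CP190-positive class (summit
#' window overlaps a CP190 peak window by >= 1 bp) and the rest, then
#' counts, per split, overlaps with each partner interval set and with
#' their union ("co-localized with sites for either of" the partners).
#'
#' @param reference_peaks reference peak set (non-empty)
#' @param cp190_peaks CP190 peak set defining the split
#' @param partner_sets named list of interval data frames
#' @param flank summit-window half-width for standardization
#' @param chrom_sizes chromosome lengths for window clipping
#' @return data frame with one row per split (`with_cp190`,
#'   `without_cp190`): `n`, per-partner counts, `union_count`,
#'   `union_fraction`
#' @export
colocalization_counts <- function(reference_peaks, cp190_peaks,
                                  partner_sets = list(), flank = 250,
                                  chrom_sizes = NULL) {
  if (!nrow(reference_peaks)) {
    stop("colocalization_counts: empty reference peak set")
  }
  win <- summit_window(reference_peaks, flank, chrom_sizes)
  with_cp <- if (!is.null(cp190_peaks) && nrow(cp190_peaks)) {
    overlap_any(win, summit_window(cp190_peaks, flank, chrom_sizes))
  } else {
    rep(FALSE, nrow(win))
  }
  splits <- list(with_cp190 = which(with_cp), without_cp190 = which(!with_cp))
  hit_mat <- matrix(FALSE, nrow(win), length(partner_sets))
  for (k in seq_along(partner_sets)) {
    hit_mat[, k] <- overlap_any(win, partner_sets[[k]])
  }
  any_hit <- if (length(partner_sets)) rowSums(hit_mat) > 0 else rep(FALSE, nrow(win))
  rows <- lapply(names(splits), function(nm) {
    i <- splits[[nm]]
    row <- data.frame(split = nm, n = length(i), stringsAsFactors = FALSE)
    for (k in seq_along(partner_sets)) {
      row[[paste0("n_", names(partner_sets)[k])]] <- sum(hit_mat[i, k])
    }
    row$union_count <- sum(any_hit[i])
    row$union_fraction <- if (length(i)) sum(any_hit[i]) / length(i) else NA_real_
    row
  })
  do.call(rbind, rows)
}
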