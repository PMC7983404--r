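#' Per-peak four-sample signal table
#'
#' One row per analysis-universe peak with the mean RPKM of the four
#' ChIP samples (FLAG and CP190 in the wild-type and mutant genotypes)
#' over the standardized summit window, the FLAG log2 fold change
#' between genotypes, and the motif flag. A pseudocount `c` guards the
#' ratio against zero signal:
#' `log2fc_flag = log2((flag_wt + c) / (flag_mut + c))`.
#' Outlier flags and group labels stay unset until
#' [partition_groups()].
#'
#' @param pk peak data frame (the cross-genotype universe)
#' @param tracks named list of RPKM `coverage_track`s: `flag_wt`,
#'   `flag_mut`, `cp190_wt`, `cp190_mut`
#' @param motif_flags logical vector, one flag per peak
#' @param pseudocount RPKM pseudocount `c` (default 0.5)
#' @param flank summit-window half-width (default 250)
#' @return a `peak_signal_table` data frame
#' @export
build_signal_table <- function(pk, tracks, motif_flags, pseudocount = 0.5,
                               flank = 250) {
  need <- c("flag_wt", "flag_mut", "cp190_wt", "cp190_mut")
  if (!all(need %in% names(tracks))) {
    stop("build_signal_table: tracks must be named ",
         paste(need, collapse = ", "))
  }
  for (nm in need) {
    if (tracks[[nm]]$normalization != "RPKM") {
      stop("build_signal_table: track ", nm, " is not RPKM-normalized")
    }
  }
  if (length(motif_flags) != nrow(pk)) {
    stop("build_signal_table: need one motif flag per peak")
  }
  win <- summit_window(pk, flank, tracks$flag_wt$chrom_sizes)
  tab <- data.frame(peak_id = sprintf("peak_%04d", seq_len(nrow(pk))),
                    chrom = pk$chrom, start = win$start, end = win$end,
                    summit = summit_pos(pk), stringsAsFactors = FALSE)
  for (nm in need) tab[[nm]] <- mean_signal(tracks[[nm]], win)
  tab$log2fc_flag <- log2((tab$flag_wt + pseudocount) /
                            (tab$flag_mut + pseudocount))
  tab$has_motif <- as.logical(motif_flags)
  tab$is_outlier <- NA
  tab$group <- NA_character_
  attr(tab, "pseudocount") <- pseudocount
  class(tab) <- c("peak_signal_table", "data.frame")
  tab
}

#' Map motif and outlier flags to the three-group partition
#'
#' GROUP1 = motif sites whose FLAG signal is a detected upper outlier
#' of the log2 fold-change distribution (binding depends on the
#' cofactor interaction); GROUP2 = motif sites without such depletion;
#' GROUP3 = sites without the motif (non-motif outliers stay in GROUP3
#' but keep their `is_outlier` flag). The three groups always
#' partition the table and |GROUP1| + |GROUP2| equals the number of
#' motif sites.
#'
#' @param tab a `peak_signal_table` with `has_motif` and `is_outlier`
#'   populated
#' @return the table with `group` assigned
#' @export
assign_groups <- function(tab) {
  stopifnot(all(c("has_motif", "is_outlier") %in% names(tab)))
  out <- ifelse(!tab$has_motif, "GROUP3",
                ifelse(tab$is_outlier %in% TRUE, "GROUP1", "GROUP2"))
  tab$group <- out
  tab
}

#' Partition peaks into depletion groups by iterative Grubbs
#'
#' Runs [iterative_grubbs()] independently on the FLAG log2
#' fold-change values of the motif and non-motif subsets (the two
#' distributions are reported separately in this analysis design),
#' flags detected upper outliers, optionally intersects the motif
#' outliers with a minimum fold-change filter, and assigns groups via
#' [assign_groups()]. Subsets with fewer than 3 peaks get no outliers
#' (with a warning).
#'
#' @param tab a `peak_signal_table`
#' @param alpha Grubbs significance level per iteration (default 0.05)
#' @param min_fold optional minimum wt/mut fold change (e.g. 2) that a
#'   motif outlier must additionally reach to enter GROUP1; `NULL`
#'   (default) disables the filter
#' @return the table with `is_outlier` and `group` populated; the two
#'   `grubbs_result`s are attached as attribute `grubbs`
#' @export
partition_groups <- function(tab, alpha = 0.05, min_fold = NULL) {
  tab$is_outlier <- FALSE
  gr <- list(motif = NULL, no_motif = NULL)
  for (subset in c("motif", "no_motif")) {
    sel <- if (subset == "motif") tab$has_motif else !tab$has_motif
    i <- which(sel)
    if (length(i) < 3) {
      if (length(i)) warning("partition_groups: ", subset,
                             " subset has < 3 peaks; no outlier testing")
      next
    }
    if (stats::sd(tab$log2fc_flag[i]) == 0) next
    g <- iterative_grubbs(tab$log2fc_flag[i], alpha = alpha)
    gr[[subset]] <- g
    tab$is_outlier[i[g$outlier_indices]] <- TRUE
  }
  if (!is.null(min_fold)) {
    c0 <- attr(tab, "pseudocount")
    fold <- (tab$flag_wt + c0) / (tab$flag_mut + c0)
    tab$is_outlier <- tab$is_outlier & (!tab$has_motif | fold >= min_fold)
  }
  tab <- assign_groups(tab)
  attr(tab, "grubbs") <- gr
  tab
}

#' Write / read a peak signal table as TSV
#' @param tab a `peak_signal_table`
#' @param path TSV path
#' @export
write_signal_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_table
#' @param pseudocount pseudocount recorded with the table
#' @export
read_signal_table <- function(path, pseudocount = 0.5) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  attr(tab, "pseudocount") <- pseudocount
  class(tab) <- c("peak_signal_table", "data.frame")
  tab
}
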