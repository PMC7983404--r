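#' Pipeline configuration
#'
#' Collects every path and tunable parameter of the end-to-end run.
#' Fragment paths are organized as
#' `paths$fragments[[sample]][[genotype]]` (character vector, one BED
#' per replicate) plus `paths$control[[genotype]]`; `paths$genome`,
#' `paths$pwm`, `paths$chrom_sizes` are required for classification,
#' `paths$blacklist` and `paths$partner_sets` are optional.
#'
#' @param paths named list of input paths (see Details)
#' @param out_dir output directory for all written artifacts
#' @param p_threshold peak-calling p-value cutoff (default 1e-2)
#' @param motif_p motif score-threshold tail probability (default 1e-4)
#' @param alpha Grubbs significance level (default 0.05)
#' @param flank summit-window half-width in bp (default 250)
#' @param search_flank extra motif search margin in bp (default 250)
#' @param bin_width coverage bin width in bp (default 100)
#' @param pseudocount RPKM pseudocount for fold changes (default 0.5)
#' @param seed seed for all stochastic steps (pseudo-replicate splits)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(paths = list(), out_dir = ".",
                            p_threshold = 1e-2, motif_p = 1e-4, alpha = 0.05,
                            flank = 250, search_flank = 250, bin_width = 100,
                            pseudocount = 0.5, seed = 1L) {
  cfg <- list(paths = paths, out_dir = out_dir, p_threshold = p_threshold,
              motif_p = motif_p, alpha = alpha, flank = flank,
              search_flank = search_flank, bin_width = bin_width,
              pseudocount = pseudocount, seed = as.integer(seed))
  validate_config(cfg, check_paths = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg, check_paths = TRUE) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x <= 1
  problems <- character(0)
  if (!in01(cfg$p_threshold)) problems <- c(problems, "p_threshold not in (0,1]")
  if (!in01(cfg$motif_p)) problems <- c(problems, "motif_p not in (0,1]")
  if (!in01(cfg$alpha)) problems <- c(problems, "alpha not in (0,1]")
  if (cfg$flank <= 0) problems <- c(problems, "flank must be > 0")
  if (cfg$search_flank < 0) problems <- c(problems, "search_flank must be >= 0")
  if (cfg$bin_width < 1) problems <- c(problems, "bin_width must be >= 1")
  if (cfg$pseudocount < 0) problems <- c(problems, "pseudocount must be >= 0")
  if (check_paths) {
    flat <- unlist(cfg$paths, use.names = FALSE)
    missing <- flat[!file.exists(flat)]
    if (length(missing)) {
      problems <- c(problems, paste("missing input:", missing))
    }
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(cfg)
}

#' Read / write a pipeline config as JSON
#' @param path JSON path
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$paths <- lapply(raw$paths, function(x) if (is.list(x)) x else as.list(x))
  do.call(pipeline_config, raw[setdiff(names(raw), character(0))])
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

log_msg <- function(...) message(format(Sys.time(), "[%H:%M:%S] "), ...)

#' Simulate a fixture set under a pipeline run
#'
#' Thin wrapper around [write_fixture_set()] that creates the output
#' directory, logs the scenario seed and returns the file manifest.
#'
#' @param sc a `chip_scenario`
#' @param out_dir output directory
#' @return manifest data frame
#' @export
run_simulate <- function(sc, out_dir) {
  validate_scenario(sc)
  log_msg("simulate: seed ", sc$seed, " -> ", out_dir)
  manifest <- write_fixture_set(sc, out_dir)
  log_msg("simulate: wrote ", nrow(manifest), " files")
  invisible(manifest)
}

read_fragment_reps <- function(paths) lapply(paths, read_bed)

#' Run the classification stage end-to-end
#'
#' Executes, per genotype: peak calling on each FLAG replicate and on
#' the pooled library against the genotype's input control, blacklist
#' filtering, and the replicate-reproduced peak set; then forms the
#' cross-genotype analysis universe, computes pooled RPKM coverage for
#' the four ChIP samples, annotates motif presence, builds the signal
#' table and partitions it into the three groups. Reproducibility
#' reports are computed for all four ChIP samples. Every intermediate
#' is written under `cfg$out_dir`; reruns on the same inputs and seed
#' are byte-identical.
#'
#' @param cfg a validated `pipeline_config`
#' @return (invisibly) list with `table`, `universe`, `summary`,
#'   `reports`, `tracks`, `reproduced`, `grubbs`
#' @export
run_classify <- function(cfg) {
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load inputs"
  result <- tryCatch({
    chrom_sizes <- read_chrom_sizes(cfg$paths$chrom_sizes)
    genome <- read_genome_fasta(cfg$paths$genome)
    pwm_obj <- load_pwm(cfg$paths$pwm)
    blacklist <- if (!is.null(cfg$paths$blacklist)) {
      read_bed(cfg$paths$blacklist)
    } else {
      genomic_intervals()
    }
    frags <- list()
    for (smp in c("FLAG", "CP190")) {
      for (gt in c("wt", "mut")) {
        frags[[smp]][[gt]] <- read_fragment_reps(cfg$paths$fragments[[smp]][[gt]])
      }
    }
    controls <- lapply(cfg$paths$control, read_bed)

    stage <- "peak calling"
    reproduced <- list(); reports <- list()
    for (smp in c("FLAG", "CP190")) {
      for (gt in c("wt", "mut")) {
        reps <- frags[[smp]][[gt]]
        ctl <- controls[[gt]]
        pk_rep <- lapply(reps, function(fr) {
          filter_blacklist(call_peaks(fr, ctl, cfg$p_threshold, chrom_sizes,
                                      cfg$bin_width), blacklist)
        })
        pooled <- do.call(bind_intervals, reps)
        pk_pooled <- filter_blacklist(
          call_peaks(pooled, ctl, cfg$p_threshold, chrom_sizes, cfg$bin_width),
          blacklist)
        key <- paste0(tolower(smp), "_", gt)
        reproduced[[key]] <- reproduced_peak_set(pk_rep[[1]], pk_rep[[2]],
                                                 pk_pooled, cfg$flank,
                                                 chrom_sizes)
        reports[[key]] <- consistency_ratios(reps[[1]], reps[[2]], ctl,
                                             chrom_sizes, cfg$p_threshold,
                                             cfg$flank, seed = cfg$seed)
        log_msg("classify: ", key, " reproduced peaks: ",
                nrow(reproduced[[key]]), " (RR ",
                round(reports[[key]]$rescue_ratio, 2), ", SR ",
                round(reports[[key]]$self_consistency_ratio, 2), ")")
        write_narrowpeak(reproduced[[key]],
                         file.path(cfg$out_dir, paste0(key, "_reproduced.narrowPeak")))
      }
    }

    stage <- "cross-genotype universe"
    universe <- cross_genotype_peak_set(reproduced$flag_wt, reproduced$flag_mut,
                                        cfg$flank, chrom_sizes)
    log_msg("classify: analysis universe of ", nrow(universe), " peaks")

    stage <- "coverage"
    tracks <- list()
    for (smp in c("FLAG", "CP190")) {
      for (gt in c("wt", "mut")) {
        pooled <- do.call(bind_intervals, frags[[smp]][[gt]])
        tracks[[paste0(tolower(smp), "_", gt)]] <-
          rpkm_normalize(coverage_from_fragments(pooled, cfg$bin_width,
                                                 chrom_sizes))
      }
    }

    stage <- "motif annotation"
    motif <- annotate_motif_peaks(universe, genome, pwm_obj, cfg$motif_p,
                                  cfg$flank, cfg$search_flank)

    stage <- "signal table and partition"
    tab <- build_signal_table(universe, tracks, motif, cfg$pseudocount,
                              cfg$flank)
    tab <- partition_groups(tab, alpha = cfg$alpha)
    summ <- depletion_summary(tab)

    stage <- "write outputs"
    write_narrowpeak(universe, file.path(cfg$out_dir, "universe.narrowPeak"))
    write_signal_table(tab, file.path(cfg$out_dir, "signal_table.tsv"))
    gr <- attr(tab, "grubbs")
    jsonlite::write_json(lapply(gr, unclass),
                         file.path(cfg$out_dir, "grubbs.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(lapply(reports, unclass),
                         file.path(cfg$out_dir, "reproducibility.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(per_group = summ$per_group,
                              cp190_log2fc_group1_vs_group2_p =
                                summ$cp190_log2fc_group1_vs_group2_p,
                              parameters = unclass(cfg)[setdiff(names(cfg),
                                c("paths", "out_dir"))]),
                         file.path(cfg$out_dir, "group_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(table = tab, universe = universe, summary = summ, reports = reports,
         tracks = tracks, reproduced = reproduced, grubbs = gr,
         chrom_sizes = chrom_sizes)
  }, error = function(e) {
    stop("run_classify failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Run the reporting stage
#'
#' From a [run_classify()] result, writes per-group profile matrices
#' and average profiles for the four tracks, the ranked signal curves,
#' the depletion summary and (when CP190 peaks or partner sets are
#' available) the co-localization table.
#'
#' @param cfg the `pipeline_config` used for classification
#' @param classified result list of [run_classify()]
#' @param window_flank heatmap window half-width (default 1000)
#' @return (invisibly) list of report objects
#' @export
run_report <- function(cfg, classified, window_flank = 1000) {
  need <- c("table", "universe", "tracks", "reproduced")
  miss <- setdiff(need, names(classified))
  if (length(miss)) {
    stop("run_report: missing upstream artifact(s): ",
         paste(miss, collapse = ", "))
  }
  tab <- classified$table
  out <- list(summary = depletion_summary(tab))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ranking <- (tab$flag_wt + tab$flag_mut) / 2
  for (g in c("GROUP1", "GROUP2", "GROUP3")) {
    i <- which(tab$group == g)
    if (!length(i)) {
      out$profiles[[g]] <- NULL
      log_msg("report: ", g, " absent (0 peaks)")
      next
    }
    pk_g <- data.frame(chrom = tab$chrom[i], start = tab$start[i],
                       end = tab$end[i],
                       summit_offset = tab$summit[i] - tab$start[i],
                       score = 0, p_value = 1e-3, stringsAsFactors = FALSE)
    for (trk in names(classified$tracks)) {
      pm <- suppressMessages(
        profile_matrix(classified$tracks[[trk]], pk_g, window_flank,
                       cfg$bin_width, ranking_values = ranking[i]))
      out$profiles[[g]][[trk]] <- pm
      utils::write.table(pm$matrix,
                         file.path(cfg$out_dir,
                                   sprintf("profile_%s_%s.tsv", g, trk)),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      out$average_profiles[[g]][[trk]] <- average_profile(pm)
    }
  }
  for (col in c("flag_wt", "flag_mut", "cp190_wt", "cp190_mut")) {
    out$ranked_curves[[col]] <- ranked_signal_curve(tab, col)
    utils::write.table(out$ranked_curves[[col]],
                       file.path(cfg$out_dir, sprintf("ranked_%s.tsv", col)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  partner_sets <- NULL
  if (!is.null(cfg$paths$partner_sets)) {
    partner_sets <- lapply(cfg$paths$partner_sets, read_bed)
  }
  if (!is.null(classified$reproduced$cp190_wt)) {
    out$colocalization <- colocalization_counts(
      classified$universe, classified$reproduced$cp190_wt,
      partner_sets %||% list(), cfg$flank, classified$chrom_sizes)
    utils::write.table(out$colocalization,
                       file.path(cfg$out_dir, "colocalization.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-call synthetic recovery run
#'
#' Simulates a scenario, runs the full classification in memory
#' (no files) and scores recovery against the ground truth:
#' the fraction of truly depleted motif sites assigned GROUP1, the
#' fraction of non-depleted motif sites assigned GROUP1, and the
#' GROUP1-vs-GROUP2 CP190 rank-sum p-value. This is the workhorse of
#' the end-to-end acceptance checks.
#'
#' @param sc a `chip_scenario`
#' @param seed run seed (overrides `sc$seed`)
#' @param pwm_obj PWM to plant and scan
#' @param cfg pipeline parameters (paths ignored)
#' @return list with the partitioned `table`, `truth` matched to the
#'   universe, and scalar metrics
#' @export
synthetic_recovery <- function(sc, seed = sc$seed, pwm_obj = pita_pwm(),
                               cfg = pipeline_config()) {
  sc$seed <- as.integer(seed)
  sim <- simulate_genome(sc, pwm_obj)
  chrom_sizes <- sc$chrom_sizes
  reproduced <- list()
  for (gt in c("wt", "mut")) {
    ctl <- simulate_fragments(sc, sim$truth, "input", gt, 1)
    reps <- lapply(seq_len(sc$n_replicates), function(r) {
      simulate_fragments(sc, sim$truth, "FLAG", gt, r)
    })
    pk_rep <- lapply(reps, call_peaks, control = ctl,
                     p_threshold = cfg$p_threshold, chrom_sizes = chrom_sizes,
                     bin_width = cfg$bin_width)
    pk_pooled <- call_peaks(do.call(bind_intervals, reps), ctl, cfg$p_threshold,
                            chrom_sizes, cfg$bin_width)
    reproduced[[gt]] <- reproduced_peak_set(pk_rep[[1]], pk_rep[[2]],
                                            pk_pooled, cfg$flank, chrom_sizes)
  }
  universe <- cross_genotype_peak_set(reproduced$wt, reproduced$mut,
                                      cfg$flank, chrom_sizes)
  tracks <- list()
  for (smp in c("FLAG", "CP190")) {
    for (gt in c("wt", "mut")) {
      pooled <- do.call(bind_intervals, lapply(seq_len(sc$n_replicates), function(r) {
        simulate_fragments(sc, sim$truth, smp, gt, r)
      }))
      tracks[[paste0(tolower(smp), "_", gt)]] <-
        rpkm_normalize(coverage_from_fragments(pooled, cfg$bin_width,
                                               chrom_sizes))
    }
  }
  motif <- annotate_motif_peaks(universe, sim$genome, pwm_obj, cfg$motif_p,
                                cfg$flank, cfg$search_flank)
  tab <- build_signal_table(universe, tracks, motif, cfg$pseudocount,
                            cfg$flank)
  tab <- partition_groups(tab, alpha = cfg$alpha)
  # match universe peaks to true sites by summit-window overlap
  win <- summit_window(universe, cfg$flank, chrom_sizes)
  truth_win <- data.frame(chrom = sim$truth$chrom,
                          start = sim$truth$center - cfg$flank,
                          end = sim$truth$center + cfg$flank)
  match_idx <- rep(NA_integer_, nrow(universe))
  for (chr in unique(win$chrom)) {
    qi <- which(win$chrom == chr); si <- which(truth_win$chrom == chr)
    if (!length(si)) next
    q <- IRanges::IRanges(as.integer(win$start[qi]) + 1L,
                          as.integer(win$end[qi]))
    s <- IRanges::IRanges(as.integer(truth_win$start[si]) + 1L,
                          as.integer(truth_win$end[si]))
    hit <- IRanges::findOverlaps(q, s, select = "first")
    match_idx[qi] <- si[hit]
  }
  matched <- !is.na(match_idx)
  truth_m <- sim$truth[match_idx[matched], , drop = FALSE]
  tab_m <- tab[matched, , drop = FALSE]
  dep_total <- sum(sim$truth$is_depleted)
  dep_in_g1 <- sum(truth_m$is_depleted & tab_m$group == "GROUP1")
  nondep_motif <- sum(truth_m$has_motif & !truth_m$is_depleted)
  nondep_in_g1 <- sum(truth_m$has_motif & !truth_m$is_depleted &
                        tab_m$group == "GROUP1")
  list(table = tab, truth = sim$truth, matched_truth = truth_m,
       matched_table = tab_m,
       metrics = list(
         n_universe = nrow(universe),
         depleted_recall = if (dep_total) dep_in_g1 / dep_total else NA_real_,
         nondepleted_fpr = if (nondep_motif) nondep_in_g1 / nondep_motif else NA_real_,
         ranksum_p = depletion_summary(tab)$cp190_log2fc_group1_vs_group2_p))
}
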