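#' Synthetic two-genotype ChIP-seq scenario
#'
#' Parameterizes a desk-scale emulation of a paired FLAG/CP190 ChIP-seq
#' design: two genotypes ("wt" and "mut", the latter carrying a protein
#' variant that cannot recruit its CP190 cofactor), two biological
#' replicates per sample, and a shared preimmune-style input control
#' per genotype. Fragments are emitted as aligned, deduplicated
#' intervals (the stand-in for post-alignment BAMs).
#'
#' Peak fragment intensities are lognormal around `flag_enrichment`
#' (mean center fold-enrichment over background). At sites flagged as
#' depleted, the mutant FLAG intensity is `depletion_factor` times the
#' wild-type intensity, and the CP190 intensity drops by the fraction
#' of CP190 recruitment attributable to the protein
#' (`cp190_coupling`).
#'
#' @param chrom_sizes named vector of chromosome lengths (bp)
#' @param n_peaks number of planted binding sites
#' @param motif_fraction probability a site carries a planted motif
#' @param depleted_fraction probability a motif site is
#'   mutant-depleted
#' @param flag_enrichment mean fold-enrichment of FLAG fragment density
#'   at a peak center over background (> 1)
#' @param enrichment_sdlog lognormal sd (log scale) of per-site
#'   enrichment heterogeneity
#' @param depletion_factor multiplicative FLAG intensity reduction in
#'   "mut" at depleted sites, in (0, 1)
#' @param cp190_coupling fraction of CP190 intensity at a site
#'   attributable to the assayed protein, in \[0, 1\]
#' @param background_rate background fragment weight per bp (only its
#'   size relative to peak weights matters once `read_depth` is fixed)
#' @param fragment_length_mean,fragment_length_sd insert-size model
#'   (bp); lengths are Normal truncated to
#'   `[50, 2 * fragment_length_mean]`
#' @param read_depth fragments per sample library (per replicate)
#' @param n_replicates biological replicates per sample
#' @param min_spacing minimum distance between planted peak centers
#' @param seed scenario base seed
#' @return a validated `chip_scenario` list
#' @export
chip_scenario <- function(chrom_sizes = c(chrS1 = 2e6, chrS2 = 2e6),
                          n_peaks = 300,
                          motif_fraction = 0.5,
                          depleted_fraction = 0.1,
                          flag_enrichment = 8,
                          enrichment_sdlog = 0.4,
                          depletion_factor = 0.25,
                          cp190_coupling = 0.9,
                          background_rate = 0.05,
                          fragment_length_mean = 156,
                          fragment_length_sd = 30,
                          read_depth = 2e5,
                          n_replicates = 2,
                          min_spacing = 2000,
                          seed = 1L) {
  sc <- list(chrom_sizes = chrom_sizes, n_peaks = n_peaks,
             motif_fraction = motif_fraction,
             depleted_fraction = depleted_fraction,
             flag_enrichment = flag_enrichment,
             enrichment_sdlog = enrichment_sdlog,
             depletion_factor = depletion_factor,
             cp190_coupling = cp190_coupling,
             background_rate = background_rate,
             fragment_length_mean = fragment_length_mean,
             fragment_length_sd = fragment_length_sd,
             read_depth = read_depth, n_replicates = n_replicates,
             min_spacing = min_spacing, seed = as.integer(seed))
  validate_scenario(sc)
  class(sc) <- "chip_scenario"
  sc
}

validate_scenario <- function(sc) {
  probs <- c(motif_fraction = sc$motif_fraction,
             depleted_fraction = sc$depleted_fraction,
             cp190_coupling = sc$cp190_coupling)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) stop("scenario: probabilities outside [0,1]: ",
                        paste(bad, collapse = ", "))
  if (sc$flag_enrichment <= 1) stop("scenario: flag_enrichment must be > 1")
  if (sc$depletion_factor <= 0 || sc$depletion_factor >= 1) {
    stop("scenario: depletion_factor must be in (0, 1)")
  }
  if (sc$read_depth <= 0) stop("scenario: read_depth must be > 0")
  if (is.null(names(sc$chrom_sizes)) || any(sc$chrom_sizes <= 0)) {
    stop("scenario: chrom_sizes must be a named vector of positive lengths")
  }
  invisible(sc)
}

peak_sd <- function(sc) sc$fragment_length_mean / 2

# deterministic per-file seed, kept well under 2^31
stream_seed <- function(seed, sample, genotype, replicate) {
  si <- match(sample, c("FLAG", "CP190", "input"))
  gi <- match(genotype, c("wt", "mut"))
  (as.integer(seed) %% 20000000L) * 100L + si * 20L + gi * 10L + as.integer(replicate)
}

#' Simulate a genome with planted binding sites
#'
#' Draws i.i.d. uniform background nucleotides, places `n_peaks` peak
#' centers at least `min_spacing` bp apart, and plants the maximum-score
#' word of `pwm` at the center of every motif-carrying site. Returns
#' the ground-truth table used by all recovery tests: per site the
#' 500 bp interval around the center, motif/depletion flags, and the
#' four expected fragment intensities (FLAG/CP190 x wt/mut) implied by
#' the scenario.
#'
#' @param sc a `chip_scenario`
#' @param pwm PWM whose consensus is planted (default the bundled
#'   synthetic 15-bp zinc-finger-style matrix, [pita_pwm()])
#' @param seed integer seed (default `sc$seed`)
#' @return list with `genome` (named character vector of sequences) and
#'   `truth` (data frame of true-peak records)
#' @export
simulate_genome <- function(sc, pwm = pita_pwm(), seed = sc$seed) {
  validate_scenario(sc)
  withr::with_seed(seed, {
    sizes <- sc$chrom_sizes
    margin <- 5000
    # peaks per chromosome proportional to length (largest remainder)
    frac <- sizes / sum(sizes) * sc$n_peaks
    kk <- floor(frac)
    rem <- sc$n_peaks - sum(kk)
    if (rem > 0) {
      o <- order(frac - kk, decreasing = TRUE)
      kk[o[seq_len(rem)]] <- kk[o[seq_len(rem)]] + 1
    }
    centers <- list()
    for (chr in names(sizes)) {
      K <- kk[[chr]]
      if (K == 0) { centers[[chr]] <- numeric(0); next }
      room <- sizes[[chr]] - 2 * margin - (K - 1) * sc$min_spacing
      if (room < 0) {
        stop("simulate_genome: cannot place ", K, " peaks on ", chr,
             " with min_spacing ", sc$min_spacing)
      }
      x <- sort(runif(K, 0, room))
      centers[[chr]] <- round(margin + x + (seq_len(K) - 1) * sc$min_spacing)
    }
    n <- sum(lengths(centers))
    chrom <- rep(names(sizes), lengths(centers))
    center <- unlist(centers, use.names = FALSE)
    has_motif <- if (n) runif(n) < sc$motif_fraction else logical(0)
    is_depleted <- has_motif & (runif(n) < sc$depleted_fraction)
    h <- rlnorm(n, -sc$enrichment_sdlog^2 / 2, sc$enrichment_sdlog)
    flag_wt <- (sc$flag_enrichment - 1) * h
    flag_mut <- ifelse(is_depleted, sc$depletion_factor * flag_wt, flag_wt)
    cp_wt <- flag_wt
    cp_mut <- ifelse(is_depleted,
                     cp_wt * (1 - sc$cp190_coupling * (1 - sc$depletion_factor)),
                     cp_wt)
    truth <- data.frame(chrom = chrom, start = center - 250, end = center + 250,
                        center = center, has_motif = has_motif,
                        is_depleted = is_depleted,
                        flag_lambda_wt = flag_wt, flag_lambda_mut = flag_mut,
                        cp190_lambda_wt = cp_wt, cp190_lambda_mut = cp_mut,
                        stringsAsFactors = FALSE)
    word <- consensus_word(pwm)
    wl <- length(word)
    genome <- vapply(names(sizes), function(chr) {
      base <- sample.int(4L, sizes[[chr]], replace = TRUE)
      idx <- which(truth$chrom == chr & truth$has_motif)
      for (ctr in truth$center[idx]) {
        at <- ctr - floor(wl / 2)          # 0-based word start
        base[(at + 1):(at + wl)] <- word
      }
      intToUtf8(c(65L, 67L, 71L, 84L)[base])
    }, "")
    list(genome = genome, truth = truth)
  })
}

#' Simulate one aligned-fragment library
#'
#' Fragment midpoints are drawn from a mixture of a uniform genomic
#' background and Gaussian bumps (sd = half the mean insert size) at
#' the true peak centers, with per-site intensity from the truth
#' record for the requested sample/genotype; `"input"` libraries are
#' background-only. Fragment lengths are truncated-Normal. The output
#' is sorted by position and deterministic in `(sc, truth, seed)`.
#'
#' @param sc a `chip_scenario`
#' @param truth truth table from [simulate_genome()]
#' @param sample one of `"FLAG"`, `"CP190"`, `"input"`
#' @param genotype `"wt"` or `"mut"`
#' @param replicate replicate number (enters the default seed)
#' @param seed integer seed; defaults to a deterministic stream seed
#'   derived from `sc$seed` and the sample labels
#' @return fragment interval data frame with `sc$read_depth` rows
#' @export
simulate_fragments <- function(sc, truth,
                               sample = c("FLAG", "CP190", "input"),
                               genotype = c("wt", "mut"), replicate = 1,
                               seed = NULL) {
  sample <- match.arg(sample)
  genotype <- match.arg(genotype)
  if (is.null(seed)) seed <- stream_seed(sc$seed, sample, genotype, replicate)
  sizes <- sc$chrom_sizes
  sdp <- peak_sd(sc)
  lam <- if (sample == "input" || nrow(truth) == 0) {
    numeric(nrow(truth))
  } else {
    truth[[paste0(tolower(sample), "_lambda_", genotype)]]
  }
  if (sample != "input" && is.null(lam)) stop("unknown sample/genotype column")
  withr::with_seed(seed, {
    w_bg <- sc$background_rate * as.numeric(sizes)           # per chromosome
    w_pk <- lam * sc$background_rate * sdp * sqrt(2 * pi)    # per peak
    w <- c(w_bg, w_pk)
    N <- as.integer(sc$read_depth)
    counts <- as.vector(rmultinom(1, N, w))
    nbgc <- counts[seq_along(sizes)]
    npk <- counts[-seq_along(sizes)]
    mids <- numeric(0); chrom <- character(0)
    for (j in seq_along(sizes)) {
      mids <- c(mids, runif(nbgc[j], 0, sizes[[j]]))
      chrom <- c(chrom, rep(names(sizes)[j], nbgc[j]))
    }
    if (nrow(truth)) {
      mids <- c(mids, rnorm(sum(npk), rep(truth$center, npk), sdp))
      chrom <- c(chrom, rep(truth$chrom, npk))
    }
    lo <- pnorm(50, sc$fragment_length_mean, sc$fragment_length_sd)
    hi <- pnorm(2 * sc$fragment_length_mean, sc$fragment_length_mean,
                sc$fragment_length_sd)
    len <- qnorm(runif(N, lo, hi), sc$fragment_length_mean, sc$fragment_length_sd)
    start <- round(mids - len / 2)
    end <- round(mids + len / 2)
    lim <- as.numeric(sizes[chrom])
    start <- pmax(0, pmin(start, lim - 1))
    end <- pmax(start + 1, pmin(end, lim))
    out <- data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE)
    out[order(out$chrom, out$start, out$end, method = "radix"), , drop = FALSE]
  })
}

#' Write a complete synthetic fixture set
#'
#' Emits the full experimental design to `out_dir`: one fragment BED
#' per ChIP sample/genotype/replicate plus one shared input control per
#' genotype (10 files under the default two-replicate design), the
#' genome FASTA, the ground-truth TSV and a JSON copy of the scenario.
#' A manifest with MD5 checksums and record counts is returned and
#' written alongside.
#'
#' @param sc a `chip_scenario`
#' @param out_dir output directory (created if missing)
#' @param pwm PWM planted in the genome
#' @return invisible manifest data frame (`file`, `md5`, `n_records`)
#' @export
write_fixture_set <- function(sc, out_dir, pwm = pita_pwm()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(sc, pwm)
  files <- character(0); counts <- integer(0)
  emit <- function(name, n) {
    files <<- c(files, name); counts <<- c(counts, n)
  }
  for (genotype in c("wt", "mut")) {
    for (sample in c("FLAG", "CP190")) {
      for (rep in seq_len(sc$n_replicates)) {
        fr <- simulate_fragments(sc, sim$truth, sample, genotype, rep)
        fn <- sprintf("%s_%s_rep%d.bed", tolower(sample), genotype, rep)
        write_bed(fr, file.path(out_dir, fn)); emit(fn, nrow(fr))
      }
    }
    fr <- simulate_fragments(sc, sim$truth, "input", genotype, 1)
    fn <- sprintf("input_%s.bed", genotype)
    write_bed(fr, file.path(out_dir, fn)); emit(fn, nrow(fr))
  }
  fa <- file.path(out_dir, "genome.fa")
  write_genome_fasta(sim$genome, fa); emit("genome.fa", length(sim$genome))
  tt <- file.path(out_dir, "truth.tsv")
  utils::write.table(sim$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  emit("truth.tsv", nrow(sim$truth))
  cfg <- file.path(out_dir, "scenario.json")
  jsonlite::write_json(unclass(sc), cfg, auto_unbox = TRUE, digits = NA)
  emit("scenario.json", 1L)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         n_records = counts, stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Genome FASTA helpers
#' @param genome named character vector of chromosome sequences
#' @param path FASTA path
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
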