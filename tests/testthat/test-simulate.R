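test_that("scenario validation catches bad parameterizations", {
  expect_error(chip_scenario(motif_fraction = 1.2), "probabilities")
  expect_error(chip_scenario(flag_enrichment = 1), "flag_enrichment")
  expect_error(chip_scenario(depletion_factor = 1), "depletion_factor")
  expect_error(chip_scenario(read_depth = 0), "read_depth")
  expect_error(chip_scenario(chrom_sizes = c(1e6, 1e6)), "named")
})

test_that("simulate_genome is deterministic and honors flags", {
  sc <- small_scenario()
  s1 <- simulate_genome(sc, seed = 3)
  s2 <- simulate_genome(sc, seed = 3)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 20)
  expect_equal(nchar(s1$genome), c(chrT1 = 3e5, chrT2 = 2e5),
               ignore_attr = FALSE)

  s3 <- simulate_genome(small_scenario(motif_fraction = 1), seed = 4)
  expect_true(all(s3$truth$has_motif))
  s0 <- simulate_genome(small_scenario(n_peaks = 0), seed = 5)
  expect_equal(nrow(s0$truth), 0)
  expect_error(simulate_genome(small_scenario(n_peaks = 5000), seed = 1),
               "cannot place")
})

test_that("planted peak centers respect spacing and carry the max-score word", {
  sc <- small_scenario(motif_fraction = 1)
  p <- pita_pwm()
  sim <- simulate_genome(sc, p, seed = 8)
  for (chr in names(sc$chrom_sizes)) {
    ctr <- sort(sim$truth$center[sim$truth$chrom == chr])
    if (length(ctr) > 1) expect_true(all(diff(ctr) >= sc$min_spacing))
  }
  word <- paste(c("A", "C", "G", "T")[consensus_word(p)], collapse = "")
  for (i in seq_len(nrow(sim$truth))) {
    at <- sim$truth$center[i] - floor(p$length / 2)  # 0-based
    expect_equal(substr(sim$genome[[sim$truth$chrom[i]]], at + 1, at + p$length),
                 word)
  }
  # planted words always reach the scanning threshold
  thr <- score_threshold(p, 1e-4)
  expect_gte(p$max_score, as.numeric(thr))
})

test_that("truth-table intensity invariants hold for every record (property)", {
  for (seed in 1:5) {
    sc <- small_scenario(depleted_fraction = 0.5)
    tr <- simulate_genome(sc, seed = seed)$truth
    dep <- tr$is_depleted
    expect_true(all(dep | tr$flag_lambda_mut == tr$flag_lambda_wt))
    expect_equal(tr$flag_lambda_mut[dep], sc$depletion_factor * tr$flag_lambda_wt[dep])
    expect_equal(tr$cp190_lambda_mut[dep],
                 tr$cp190_lambda_wt[dep] *
                   (1 - sc$cp190_coupling * (1 - sc$depletion_factor)))
    expect_true(all(tr$cp190_lambda_mut[!dep] == tr$cp190_lambda_wt[!dep]))
    expect_true(all(!tr$has_motif | tr$end - tr$start == 500))
  }
})

test_that("fragment libraries match the requested depth and length model", {
  sc <- small_scenario()
  sim <- simulate_genome(sc, seed = 2)
  fr <- simulate_fragments(sc, sim$truth, "FLAG", "wt", 1)
  expect_equal(nrow(fr), sc$read_depth)
  len <- fr$end - fr$start
  expect_true(all(len >= 49 & len <= 2 * sc$fragment_length_mean + 1))
  expect_equal(mean(len), sc$fragment_length_mean, tolerance = 0.02)
  # determinism via the derived stream seed
  fr2 <- simulate_fragments(sc, sim$truth, "FLAG", "wt", 1)
  expect_identical(fr, fr2)
  # different replicate -> different stream
  fr3 <- simulate_fragments(sc, sim$truth, "FLAG", "wt", 2)
  expect_false(identical(fr$start, fr3$start))
  expect_error(simulate_fragments(sc, sim$truth, "H3K27", "wt", 1))
})

test_that("input libraries ignore the truth intensities", {
  sc <- small_scenario()
  sim <- simulate_genome(sc, seed = 6)
  inp <- simulate_fragments(sc, sim$truth, "input", "wt", 1)
  # empirical depth at peak centers stays near the genome-wide background
  cov <- coverage_from_fragments(inp, 100, sc$chrom_sizes)
  win <- data.frame(chrom = sim$truth$chrom, start = sim$truth$center - 250,
                    end = sim$truth$center + 250)
  at_peaks <- mean(mean_signal(cov, win))
  genome_mean <- mean(unlist(cov$values))
  expect_equal(at_peaks, genome_mean, tolerance = 0.1)
})

test_that("depleted peaks show the prescribed mut/wt FLAG depth ratio", {
  # one strong depleted peak, Monte-Carlo over the fragment draw
  sc <- chip_scenario(chrom_sizes = c(chrT1 = 2e5), n_peaks = 1,
                      motif_fraction = 1, depleted_fraction = 1,
                      enrichment_sdlog = 1e-9, read_depth = 5e4,
                      depletion_factor = 0.25)
  sim <- simulate_genome(sc, seed = 21)
  ctr <- sim$truth$center[1]
  count_at_peak <- function(fr) {
    sum(fr$chrom == sim$truth$chrom[1] &
          (fr$start + fr$end) / 2 >= ctr - 200 &
          (fr$start + fr$end) / 2 < ctr + 200)
  }
  # empirical background midpoint density from a far-off-peak region
  bg_in_window <- function(fr) {
    m <- (fr$start + fr$end) / 2
    400 * sum(m >= ctr + 5000 & m < ctr + 45000) / 40000
  }
  wt <- simulate_fragments(sc, sim$truth, "FLAG", "wt", 1, seed = 1001)
  mut <- simulate_fragments(sc, sim$truth, "FLAG", "mut", 1, seed = 1002)
  nb_wt <- count_at_peak(wt) - bg_in_window(wt)
  nb_mut <- count_at_peak(mut) - bg_in_window(mut)
  ratio <- nb_mut / nb_wt
  se <- sqrt(count_at_peak(wt) + count_at_peak(mut)) / nb_wt
  expect_lt(abs(ratio - 0.25), 3 * (se + 0.02))
})

test_that("non-depleted peaks are genotype-independent in law", {
  sc <- small_scenario(depleted_fraction = 0, n_peaks = 40,
                       chrom_sizes = c(chrT1 = 5e5, chrT2 = 4e5))
  sim <- simulate_genome(sc, seed = 17)
  wt <- simulate_fragments(sc, sim$truth, "FLAG", "wt", 1)
  mut <- simulate_fragments(sc, sim$truth, "FLAG", "mut", 1)
  win <- data.frame(chrom = sim$truth$chrom, start = sim$truth$center - 250,
                    end = sim$truth$center + 250)
  cw <- mean_signal(coverage_from_fragments(wt, 100, sc$chrom_sizes), win)
  cm <- mean_signal(coverage_from_fragments(mut, 100, sc$chrom_sizes), win)
  expect_gt(wilcox.test(cw, cm, paired = TRUE)$p.value, 0.01)
})

test_that("write_fixture_set emits the full deterministic design", {
  sc <- small_scenario(read_depth = 5e3)
  d1 <- file.path(tempdir(), "fixt1"); d2 <- file.path(tempdir(), "fixt2")
  m1 <- write_fixture_set(sc, d1)
  m2 <- write_fixture_set(sc, d2)
  beds <- grep("\\.bed$", m1$file, value = TRUE)
  expect_length(beds, 10)  # 2 samples x 2 genotypes x 2 reps + 2 inputs
  expect_true(all(c("genome.fa", "truth.tsv", "scenario.json") %in% m1$file))
  expect_equal(m1$md5, m2$md5)  # same seed -> identical bytes
  # read-back counts match the manifest
  for (b in beds) {
    expect_equal(nrow(read_bed(file.path(d1, b))),
                 m1$n_records[m1$file == b])
  }
  # FASTA round trip
  g <- read_genome_fasta(file.path(d1, "genome.fa"))
  expect_equal(nchar(g), sc$chrom_sizes, ignore_attr = FALSE)
})
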