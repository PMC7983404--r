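# chipdep

Classify ChIP-seq binding sites by whether their binding — and the
recruitment of a partner protein — depends on a specific protein–protein
interaction.

## The problem

Insulator (architectural) DNA-binding proteins such as *Drosophila*
Pita recruit the CP190 cofactor to chromatin. Given ChIP-seq of a tagged
protein in two genotypes — wild type (`wt`) and a mutant lacking its
CP190-interaction surfaces (`mut`) — plus CP190 ChIP in both, the
analysis asks for every binding site: did binding weaken in the mutant,
and did CP190 recruitment collapse with it?

`chipdep` implements that pipeline as a tested, reusable R package:

1. **Peak calling** against an input/preimmune control: per-100 bp-bin
   Poisson test with local rate
   `λ_local = max(λ_genome, λ_5kb, λ_10kb)` from the depth-scaled
   control, `p ≤ 1e-2`, blacklist filtering.
2. **Reproducibility**: pooled peaks kept when both replicates support
   them; ENCODE-style rescue/self-consistency ratios (pass when both
   < 2) from seeded pseudo-replicate splits.
3. **Quantification** on `summit ± 250 bp` windows from RPKM coverage
   at 100 bp bins; FLAG fold change
   `log2((wt + c)/(mut + c))`, `c = 0.5`.
4. **Motif partition**: PWM scanning of both strands at an exact
   tail-probability score threshold (`p = 1e-4`), computed by dynamic
   programming over the discretized score distribution.
5. **Depletion detection**: the one-sided upper Grubbs test
   (`G = (max − mean)/sd`, critical value
   `((N−1)/√N)·√(t²_{α/N, N−2}/(N−2+t²))`), applied iteratively at
   `α = 0.05` to the fold-change distribution, separately for motif and
   non-motif sites.
6. **Groups**: GROUP1 = motif sites with depleted binding,
   GROUP2 = motif sites without, GROUP3 = non-motif sites; per-group
   CP190 summaries, ranked signal curves, profile heatmap matrices,
   co-localization counts.

A seeded synthetic generator (`chip_scenario()`, `simulate_genome()`,
`simulate_fragments()`) emulates the full experimental design — planted
motifs, per-site enrichment, mutant-depleted subsets, paired-end-like
fragment lengths (Normal(156, 30)), two replicates, shared inputs — so
every stage runs against ground truth with no external data.

## Worked example

Simulate the default scenario (300 sites on 2 × 2 Mb, 10% of motif
sites depleted at factor 0.25) and run the whole classification in
memory:

```r
library(chipdep)
sc <- chip_scenario(seed = 11)
r  <- synthetic_recovery(sc, seed = 11)
table(r$table$group)
#> GROUP1 GROUP2 GROUP3
#>     16    152    132
depletion_summary(r$table)$per_group[, c("group", "n", "flag_wt_mean",
                                         "flag_mut_mean", "cp190_mut_mean",
                                         "cp190_log2fc_mean")]
#>    group   n flag_wt_mean flag_mut_mean cp190_mut_mean cp190_log2fc_mean
#> 1 GROUP1  16         1440           608            726           0.90520
#> 2 GROUP2 152         1338          1354           1344          -0.01524
#> 3 GROUP3 132         1351          1348           1330           0.00225
```

Reading the numbers: the 16 GROUP1 sites lost over half their FLAG
signal in the mutant (1440 → 608 RPKM) and their CP190 signal dropped
with it (mean CP190 log2 wt/mut ≈ 0.9, i.e. ~1.9-fold), while GROUP2/3
are untouched — the rank-sum test of CP190 fold changes GROUP1 vs
GROUP2 gives p ≈ 5.7e-11. Against the generator's truth this run
recovers 100% of the truly depleted sites with no false GROUP1 members
(`r$metrics`).

The motif machinery is exact rather than heuristic:

```r
p <- pita_pwm()              # bundled synthetic 15-bp matrix
p
#> <pwm> 15 positions, score range [-38.824, 23.862] bits, consensus AAAACTCCATGTGTA
score_threshold(p, 1e-4)
#> 9.840 bits (achieved tail probability 9.99e-05, guaranteed <= 1e-4)
```

File-based runs mirror the same flow: `write_fixture_set()` emits the
ten fragment BEDs + genome FASTA + truth TSV,
`run_classify(pipeline_config(...))` writes narrowPeak/TSV/JSON
artifacts, `run_report()` adds profile matrices, ranked curves and
co-localization tables. A CLI wrapper (`chipdep_main()`, subcommands
`simulate` / `callpeaks` / `classify` / `report`) lives in
`inst/cli/chipdep.R`.

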