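---
title: "chipdep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chipdep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the pipeline answers

Architectural ("insulator") DNA-binding proteins such as Pita organize
chromatin partly by recruiting the CP190 cofactor through dedicated
interaction surfaces. Comparing ChIP-seq of a tagged wild-type protein
("wt") with a variant lacking its CP190-interacting regions ("mut")
asks, per binding site: does binding itself, and does CP190 recruitment,
depend on that interaction? `chipdep` implements the computational side
of this two-genotype design end to end: peak calling against a
preimmune-style input, replicate-reproducibility filtering, per-site
signal quantification, motif partitioning, outlier-based detection of
genotype-depleted sites, and per-group cofactor summaries — plus a
synthetic generator so that every stage has ground truth.

The end product is a three-way partition of the binding-site universe:

* **GROUP1** — motif-carrying sites whose FLAG (protein) signal is an
  upper outlier of the wt-vs-mut log2 fold-change distribution: binding
  there depends on the cofactor interaction;
* **GROUP2** — motif-carrying sites without such depletion;
* **GROUP3** — sites without the binding motif (upper outliers among
  them are flagged but remain in GROUP3).

## Signal model and parameters

**Peak calling.** Fragment midpoints are counted on a fixed 100 bp grid
and tested against a Poisson upper tail with
`lambda_local = max(lambda_genome, lambda_5kb, lambda_10kb)` estimated
from the depth-scaled control — the classic local-lambda enrichment
control, deliberately simplified (no model building, no broad calls)
because the scientific content of the analysis begins downstream.
Significant bins (`p <= 1e-2` by default) merge within one fragment
length; the summit is the bin of maximal treatment count (leftmost on
ties). Taking the maximum of three lambda estimates makes the caller
conservative, which is what the background-only false-positive test
verifies.

**Windows and quantification.** Every downstream statistic lives on the
standardized window `summit ± 250 bp`. Signals are RPKM
(`v · (1000/bin_width) · (1e6/total_mapped)`) averaged length-weighted
over the window. Fold changes use a pseudocount, default
`c = 0.5` RPKM: `log2((flag_wt + c)/(flag_mut + c))`; the source
analysis states no zero-guard, so the pseudocount is our choice, logged
in every output.

**Reproducibility.** Rather than the full IDR copula model, "reproduced"
means: a pooled-library peak whose window overlaps a peak in both
replicates. The rescue and self-consistency ratios are peak-count ratios
over seeded pseudo-replicate splits, with the pass criterion RR < 2 and
SR < 2. The analysis universe is the union of the two genotypes'
reproduced FLAG peak sets, merging peaks with overlapping windows and
keeping the stronger summit (the union, rather than intersection, keeps
mutant-depleted sites in the universe — they may be weak or absent in
the mutant calls).

**Motif partition.** The position weight matrix is scored in bits
against a background model (uniform by default — the scanning tool the
field uses defaults to a simple background, and nothing else is stated).
The score threshold for the 1e-4 tail probability is computed exactly by
dynamic programming over a discretized score distribution: grid
granularity 1e-3 bits, scores rounded *down* while building the
distribution and the threshold rounded *up* by one grid step per
position, which guarantees the achieved tail never exceeds the request.
The threshold is capped at the maximum attainable score so a planted
consensus word always passes whenever `p >= 4^-L`. Both strands are
scanned; windows containing N are skipped. A peak is a "motif peak" when
at least one hit overlaps its window extended by `search_flank`
(default 250 bp, i.e. summit ± 500 bp in total — our literal reading of
"± 250 bp from the peak boundaries", where the boundaries are themselves
summit ± 250; `search_flank = 0` gives the other reading).

**Outlier detection.** The one-sided upper Grubbs statistic
`G = (max − mean)/sd` is tested with the standard single-outlier
critical value `G_crit(α, N) = ((N−1)/√N)·√(t²/(N−2+t²))`, `t` the upper
`α/N` t-quantile on `N−2` degrees of freedom; the p-value is the exact
inversion of this relation. The test is applied iteratively (remove the
detected maximum, retest) while `p < 0.05`, separately on the motif and
non-motif subsets — the source reports outlier counts for each subset
separately, so separate runs are our reading. Ties at the maximum take
the leftmost index; iteration stops cleanly below 3 values or on an
(effectively) constant sample. "Effectively constant" uses a relative
1e-9 range guard: window means computed through cumulative sums leave
~1e-14 floating noise on analytically-zero fold changes, and Grubbs must
not "detect" outliers in that noise. An optional `min_fold` filter can
additionally require a ≥ 2-fold measured decrease for GROUP1 membership;
it is off by default because the outlier procedure is the primary
definition.

## The synthetic world

`chip_scenario()` defaults encode the emulated experimental design:
2 × 2 Mb chromosomes, 300 sites ≥ 2 kb apart, motif planted at 50% of
sites, 10% of motif sites mutant-depleted at factor 0.25, mean center
enrichment 8-fold over background, paired-end-like fragments of length
Normal(156, 30) truncated to [50, 312], 2 × 10^5 fragments per
replicate, two replicates per sample, one shared input per genotype.
Fragment midpoints mix a uniform background with Gaussian bumps
(sd = half the mean insert) at site centers; "input" draws background
only. CP190 intensity equals FLAG intensity at a site, and at depleted
sites drops by `cp190_coupling · (1 − depletion_factor)` (default
coupling 0.9), so cofactor recruitment collapses specifically where
binding collapses.

Two generator choices go beyond the stated design and deserve
justification:

* **Per-site enrichment heterogeneity** is lognormal with `sdlog = 0.4`
  (mean fixed at the stated 8-fold). Real ChIP peak strengths span at
  least an order of magnitude; a single-strength world would also be
  statistically misleading for the outlier procedure (see below). The
  value was chosen a priori as "realistic spread" and not revisited.
* **`background_rate`** only matters relative to the peak weights once
  `read_depth` is fixed; its default (0.05/bp) yields ~9% of fragments
  in peaks, a typical fraction for a good ChIP.

What the generator does *not* emulate: sequencing errors, mappability
and GC bias, duplicate structure, chromatin accessibility background
structure, or motif-affinity-dependent binding strength. A green
synthetic test therefore establishes that the *procedures* are correct
and calibrated on data obeying their model assumptions — not that the
biological conclusions of any particular study are right.

## Statistical behavior worth knowing about

**Background dilution bounds the measured fold change.** A depleted
site's bump loses 4-fold (factor 0.25), but the ±250 bp window also
contains background that is genotype-independent. With window
bump-to-background ratio `B`, the measured ratio is `(1+B)/(1+B/4)`,
which is ≥ 2 only for `B ≥ 2` (center enrichment ≳ 6-fold) and never
exceeds 4. Weakly enriched depleted sites can therefore measure below
2-fold while still being true outliers; conversely the "Group 1 sites
show at least a two-fold decrease" description holds for the median but
not necessarily for every site in the synthetic world. The test suite
asserts the direction for every GROUP1 site and the 2-fold mark on the
median.

**Masking makes iterative Grubbs all-or-nothing per dataset.** With 10%
of a 150-value sample shifted, the *first* Grubbs step operates at
G ≈ 3.4–4 against a critical value ≈ 3.33; once the first few outliers
are removed the cascade accelerates and typically recovers everything,
but on an unlucky draw the first step fails and nothing is detected.
Enrichment heterogeneity (which spreads the shifted values and pushes
the maximum up) is what makes the cascade start reliably. The
20-seed-averaged recovery criterion (≥ 90% of truly depleted sites in
GROUP1, ≤ 2% false inclusion) holds with this behavior included; single
seeds can fail wholesale, which is a property of the published
procedure, not of this implementation.

**Conservative choices.** The caller's max-of-lambdas control keeps the
per-bin false-positive rate below nominal; the PWM threshold's rounding
keeps the achieved motif p at or below request; the Grubbs α/N quantile
is the standard slightly-conservative single-outlier critical value
(null detection rate ≈ 0.05, verified by simulation).

## Numerical and degenerate-input policy

* Coordinates are 0-based half-open everywhere; abutting intervals do
  not overlap. narrowPeak summit `-1` maps to the interval midpoint with
  a warning.
* BedGraph and fragment coverage resample by length-weighted means;
  bins at chromosome ends average over their real bases only.
* Profile windows running off a chromosome are zero-padded and flagged.
* Empty treatment/control, zero-length intervals, unknown chromosomes,
  non-rectangular PWMs and out-of-range probabilities are errors naming
  the offending input; subsets with < 3 values skip outlier testing with
  a warning; empty groups are reported as absent rather than dropped.
* All stochastic steps (generator, pseudo-replicate splits) take
  explicit seeds; derived per-library stream seeds stay below 2^31.

## Known limitations

* The caller is a stand-in: fixed-width bins, midpoint counts, no
  fragment-model refinement — summit resolution is limited to the bin
  grid (the recovery criterion's 100 bp tolerance reflects that).
* The IDR replacement is overlap-based; the RR definition follows this
  package's contract (ratio of the two pooled pseudo-replicate counts)
  rather than the ENCODE rescue ratio, though the counts needed for the
  ENCODE form are all reported.
* The bundled 15-bp PWM is a synthetic stand-in with a fixed consensus;
  analyses of real data must supply the real matrix.
* Co-localization fractions depend entirely on the supplied partner
  peak sets; the package computes the statistic but ships no external
  datasets.
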