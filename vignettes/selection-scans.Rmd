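---
title: "Detecting parallel selection in replicated chicken populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel selection in replicated chicken populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The two screens and their logic

Modern commercial chicken derives from replicated, independently bred
populations pushed toward similar goals: white and brown egg layers on one
side, meat-type broilers on the other. `sweepscan` implements two
complementary screens over whole-genome SNP data that exploit this
replication.

The **parallel-fixation screen** asks whether the *same* allele sits at
high frequency in every population. Under drift alone, fixation events are
independent across populations, so the probability that one allele is near
fixation everywhere falls off geometrically with the number of replicates;
under selection on a shared target it does not. The decision statistic for
a 40 kb window is the minimum, across populations, of the window-mean
alternate-allele frequency: the "elevated in all populations" criterion is
exactly `min ≥ τ`. Because the alternate allele is counted relative to one
shared reference in every population, an elevated minimum always refers to
one allele, not to a different allele per population.

The **parallel-divergence screen** asks where the layer group and the
broiler group have been pulled apart. Per-site Fst is the Weir & Cockerham
(1984) estimator θ̂ = a/(a+b+c), computed from the two group allele
frequencies and haplotype-equivalent sample sizes. Window means are
thresholded at the empirical top 1% of all windows; this is an outlier
scan, deliberately free of a null model — the threshold adapts to whatever
genome-wide differentiation the data carry. Flagged windows are clustered
into regions, because a hard sweep's hitchhiking footprint spans many
overlapping windows, and each region reports its maximum window Fst and
the minimum self-inclusive empirical percentile P of its members.

Both screens are deterministic given their inputs and configuration; every
result object carries the resolved configuration so a run can be
reproduced from its output.

## The estimator, and which "mean Fst" is which

Weir and Cockerham's variance components are computed here from group
frequencies with the heterozygosity term replaced by its Hardy–Weinberg
expectation 2p(1−p). Observed genotypic heterozygosity simply does not
exist for pool-sequenced broilers, and applying the same convention to the
layers keeps the two sides symmetric (`scan_config(layer_combine =
"pooled")` switches the layer group from the unweighted mean of the two
population tracks to a haplotype-weighted pool, which matters only when
the layer sample sizes differ).

Two distinct summaries are exposed deliberately:

* `wc_fst_site()` — per-site θ̂, the quantity that is window-averaged. Sites
  where both groups are fixed for the same allele are undefined and
  excluded; small negative values are legitimate estimator behavior under
  no differentiation and are retained in window means (clamping would bias
  the background upward).
* `wc_fst_global()` — the 1984 multi-locus estimator Σa/Σ(a+b+c). This is
  the genome-wide figure. The arithmetic mean of per-site ratios is
  systematically dragged below the drift parameter by low-information
  sites, which is easy to verify on simulated panels; the ratio-of-sums
  form recovers the generator's F and is the quantity the acceptance
  script reports as `baseline_fst_recovered`.

Pooled sample sizes enter as read counts, optionally capped at twice the
pool's diploid size (`pool_size`) so that deep sequencing of a small pool
cannot overstate precision. The Hudson estimator is provided as an
independent cross-check; at balanced sample sizes the two agree to three
decimals, and the test suite pins the divergence bound at unbalanced sizes.

## Window frame and coordinate conventions

Windows of 40 kb advance in 5 kb steps, anchored at coordinate 0 of each
chromosome, and only full-width windows are kept — trailing partial windows
would carry a different variance and contaminate an outlier scan. Each
interior site therefore contributes to 8 consecutive windows. Window means
require `min_snps_per_window` (default 5) contributing sites; at ~107 bp
SNP spacing a real 40 kb window holds several hundred SNPs, so the default
only suppresses pathological windows, but it is configurable for sparser
panels.

Positions are 0-based half-open internally (unambiguous window
arithmetic); all reported regions are 1-based inclusive, the convention of
published candidate tables, and BED/BEDGRAPH exports convert back to
0-based.

The top-1% rule is a nearest-rank quantile implemented as a set-size
contract: the threshold is the value such that `{v ≥ t}` holds exactly
`⌈0.01·N⌉` windows for distinct values, with ties at the threshold flagged
inclusively (ties can only enlarge the set, never silently shrink it). A
small epsilon guards the ceiling against floating-point noise in
`(1−q)·N`. Empirical P is self-inclusive, so the most extreme window gets
`1/N`, never 0. A region's P is the minimum over member windows, pairing
naturally with the maximum member Fst; a per-region percentile over merged
spans would be the alternative reading, and nothing in the merging step
precludes computing it downstream from the exported window track.

Threshold inclusivity in the fixation screen is `≥ τ` with τ = 0.85: the
published candidate table this package bundles contains a region sitting
exactly at 0.85 in one population, so the strict inequality would
contradict the table it mirrors. τ is a parameter, not a constant.

## Ingestion filters

`read_vcf()` keeps biallelic SNPs only (multi-allelic records and indels
are dropped and counted, not decomposed), requires Phred site quality ≥ 20
(99% call accuracy), and applies a read-depth band of mean ± 2 SD computed
over the incoming site set in a single pass — excess depth marks collapsed
repeats, deficient depth unreliable calls. The band is global rather than
per-chromosome; a per-chromosome band would let chromosome-scale coverage
differences silently shift the filter. Pooled sites with fewer than
`min_pool_depth = 4` reads in a pool are *masked* for that pool rather than
dropped, so site frames stay aligned across populations; a frequency from
three reads is too noisy to window-average, yet removing the site would
desynchronize the tracks. `intersect_sites()` restricts tables to their
common sites, harmonizes swapped ref/alt orientations by complementing
dosages and counts (logged), and drops irreconcilable alleles (counted).

## Haplotype statistics

EHH at offset x is the probability that two random carrier chromosomes of
the core allele are identical at every site between the core and x; it is
1 at the core and non-increasing outward, which the implementation asserts
by construction (prefix-group refinement). iHS integrates EHH over
physical distance by the trapezoid rule, both directions, separately for
ancestral and derived carriers, and takes `ln(iHH_A/iHH_D)`; scores are
standardized within 20 equal-width derived-allele-frequency bins. The
standard parameters of the method's original description are the defaults:
EHH truncation 0.05, MAF cutoff 0.05, maximum tolerated inter-site gap
200 kb. Cores whose curves hit the chromosome edge or a larger gap while
still above the truncation level are reported as missing rather than
integrated short — an incomplete integral is biased toward zero and would
dilute exactly the signal the statistic exists to find. Physical distance
stands in for genetic distance: no chicken linkage map ships with the
package and the generator has uniform recombination by construction, so a
map would add a dependency without changing any simulated result.
Unphased input is a hard error, not something to phase silently — guessing
phase corrupts the statistic in unbounded ways.

## What the generator emulates, and what it does not

`simulate_panel()` mirrors the study design: two phased layer populations
of 25 diploids, three broiler pools with Poisson read depth (mean 30, a
typical pool-seq coverage), SNP positions with exponential spacing at mean
107 bp, ancestral frequencies uniform on (0.05, 0.95), and per-population
frequencies from the Balding–Nichols model with F = 0.18. Balding–Nichols
was chosen over forward simulation because it gives direct control of the
single differentiation parameter the screens are calibrated against, with
no demographic assumptions to defend.

Hard sweeps are implanted on top: the allele-frequency excess at distance
d from the center decays as `exp(−d/L)`, applied exactly at the frequency
level for pools, and through a nested forced-carrier set for genotyped
populations when `core_haplotype = TRUE`. The carrier fraction is anchored
at the population's mean background frequency and decays smoothly with
distance, so the forced set is nested and contiguous — near-core carriers
share one long haplotype, the footprint iHS detects — while per-site
frequencies still follow the hitchhiking decay in expectation.

Deliberate simplifications, and what they imply about test coverage:
neutral sites are drawn independently (no background linkage
disequilibrium), recombination is implicitly uniform, there is no
ascertainment bias, no sequencing error in genotypes, and pool depth is
the only pool-seq noise source. Passing tests therefore demonstrate that
the *machinery* is correct and has power against clean hard sweeps; they
do not demonstrate robustness to background LD, soft sweeps, bottlenecks,
or reference bias, all of which real data carry. The empirical-percentile
design of the divergence screen is the main defense: its threshold adapts
to the realized background, whatever produced it.

## Problem sizes and frozen tolerances

The test suite and acceptance script run on deliberately modest instances:
drift-parameter recovery uses replicate panels of one 1.07 Mb chromosome
(~10,000 SNPs) and checks the multi-locus estimate within ±0.02 of
F = 0.18 across replicates; sweep-recovery power uses 100 replicates per
screen on 600 kb chromosomes with `p_sweep = 0.95`, `L = 100 kb`, and
requires the implanted center inside a reported region in ≥95; iHS power
uses 50 replicates on 80 kb chromosomes with a `daf ≈ 0.8` core-haplotype
sweep, compared as paired differences of mean |iHS| inside versus across
the panel. The Weir–Cockerham implementation is checked against an
independently written scalar transcription of the 1984 variance components
to 1e−12 over 10,000 random frequency/sample-size tuples, and the iHS
machinery against exhaustive pair enumeration on panels small enough to
enumerate, including a 4-haplotype toy panel whose score reduces to
`log(4/7)` by hand.

## Known limitations

Pool-seq frequencies carry binomial read-sampling noise that the window
mean averages but does not model; a likelihood-based pool estimator is out
of scope. The fixation screen's τ is a single global constant, not
frequency-dependent. Region merging uses strict grid adjacency by default
(`gap_tolerance` relaxes it); published region counts from any real study
depend on unstated merging conventions, so region-level comparisons across
tools should use the exported window tracks, not region counts. The
micro/macro chromosome classification (GGA1–5 macro, 6–10 intermediate,
11+ micro) is a convention, exposed as an overridable map rather than
hard-coded truth.
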