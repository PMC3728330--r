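---
title: "Methods: pooled extreme-segregant QTL mapping in bsaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled extreme-segregant QTL mapping in bsaqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
model behind each stage, the tunable parameters and their defaults, the
design of the synthetic-data generator, the numerical choices, and the
known limitations. It states no empirical numbers beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The experimental design being analysed

Two inbred parents are crossed; the selfed F2 is selfed again to give a
large F3 population segregating for a quantitative trait. The extreme low
tail (ES) and extreme high tail (ET) — a few percent of the population
each — are pooled and each pool is shotgun-sequenced. At every SNP that
distinguishes the parents we observe the 2x2 table of read depths
(pool x parental allele), `n1, n2` in ES and `n3, n4` in ET, with `n1`,
`n3` counting the parent-1 (reference) allele.

Away from QTLs both pools estimate the same allele frequency (about 1/2 in
an F3); near a QTL truncation selection shifts the two pools in opposite
directions. Everything downstream is a formalization of "where do the two
pools disagree more than sampling noise allows".

## 2. Stage by stage

### Read quality control (`mott_trim`, `filter_read`, `trim_fastq`)

Modified Mott trimming scores base `i` as `limit - p_i`, where
`p_i = 10^(-q_i/10)` and `limit = 0.05` by default, and retains the
contiguous segment with maximal score sum; if every score is negative the
read is discarded. `N` bases are scored with `p = 0.75` regardless of
their stated quality, so a run of ambiguous bases can never rescue a
segment. Trimmed reads shorter than 25 bp or with more than 2 `N`s are
dropped. Ties among equal-sum segments go to the leftmost, then longest,
segment — this makes trimming deterministic and idempotent, which the
suite checks against an exhaustive all-substrings oracle. Only
Sanger/PHRED+33 FASTQ is accepted; other encodings are rejected rather
than guessed.

### SNP filtering (`filter_snps`)

Three retention rules guard against segregation-distorted and
depth-unstable tables: overall parent-1 frequency within [0.20, 0.80],
total depth within [100, 400], and each pool at least 40x. The interval
bounds are closed ("neither < 100 nor > 400" admits 100 and 400). A SNP
failing several rules is attributed to the first failing rule in the
order frequency, total depth, pool depth; a zero-depth SNP has no defined
frequency and is rejected under the depth rule. Frequencies are computed
from read depths, never from genotype calls — a pooled design has no
per-individual genotypes.

### The G and G′ scan (`g_statistic`, `gprime_scan`)

`G = 2 * sum_i n_i ln(n_i / n̂_i)` with margin-preserving expectations
`n̂_i`; `0 ln 0 = 0`. `G'` at a SNP is the weighted mean of G over all
SNPs within ±500 kb (window 1000 kb), with tricube weights
`(1 - D^3)^3` in the standardized distance `D` (0 at the centre, 1 at the
edge), renormalized to sum to one within each window. Windows never cross
chromosome boundaries and truncate at chromosome ends. If a window
degenerates to edge SNPs only (all raw weights zero), G′ falls back to the
centre SNP's own G, avoiding 0/0. Window membership uses the closed
condition `|pos_j - centre| <= 500 kb`; edge SNPs carry zero weight, so
the choice of open versus closed edges is immaterial.

Renormalizing weights per window (rather than using a fixed denominator)
makes G′ a weighted average, so `min G <= G' <= max G` within each
window; the suite asserts this and checks a 5-SNP window against direct
hand evaluation.

### The empirical null and FDR threshold (`estimate_threshold`)

G′ in non-QTL regions is modelled as log-normal; the observed G′
distribution is that null contaminated by QTL regions. The procedure:

1. Exclude putative QTL regions. By default these are found from a
   preliminary trimmed fit on all G′ values: SNPs with p < 0.001, merged
   across gaps up to 1 Mb. An explicit interval table can override.
2. Twenty times: draw one G′ per 200-kb bin (bins anchored at position 1
   per chromosome, final partial bin kept) outside the excluded regions;
   trim (`x = ln G'`, drop `x - Median(x) > 5.2 Median(z)` with `z` the
   lower-half deviations); fit `mu = ln Median`, `sigma2 = mu - ln Mode`.
   The final parameters are the means over repetitions.
3. Per repetition, draw a genome-wide one-per-bin G′ subsample (QTL
   regions included), compute upper-tail p-values under the averaged
   null, and apply the Benjamini–Hochberg step-up rule at `q* = 0.05`.
   The selected `p_k` values are averaged over the repetitions that
   select anything, and the average is inverted through the log-normal
   quantile to the G′ threshold.

Averaging `p_k` and inverting once (rather than averaging per-repetition
thresholds) keeps the quantile-inversion identity between `p_threshold`
and `gprime_threshold` exact, and is symmetric with the averaging of the
null parameters. The threshold is then applied to all SNPs genome-wide:
the 200-kb spacing (about 1 cM in a rice-scale genome) exists to decimate
the strong local correlation of G′, and the skipped values carry no
additional information.

Two degeneracies are handled explicitly. A subsample can be too weakly
right-skewed to fit (estimated mode at or above the median); such
repetitions are skipped, and if all twenty fail the null is fitted once on
the full non-excluded track (with a warning). If even that aggregate shows
no right skew — which happens systematically on large, perfectly null
tracks, where `ln G'` (the log of an effectively high-degree-of-freedom
average) is mildly *left*-skewed — there are no contaminating components
to separate, no log-normal null to fit, and nothing that could be called
significant: a no-signal model with an infinite threshold is returned
with a warning. Likewise, if no repetition rejects anything under BH, the
threshold is `+Inf` — the scan simply found nothing.

### Differential SNPs (`differential_scan`)

The Jensen–Shannon divergence between the pools' allele distributions is
computed with depth weights `(N_ES/N, N_ET/N)`; then `2 N JSD` (nats)
equals the likelihood-ratio G exactly, which makes the chi-squared(1)
calibration of the test principled and the two scans provably consistent.
The equal-weight JSD variant would lose both properties. Significance uses
Bonferroni at overall level 0.05 across all tested SNPs.

### NAFD profile (`nafd_scan`)

The parent-1 allele frequency of a 300-kb window in one pool is the
depth-pooled ratio `sum(a_i) / sum(a_i + b_i)` over the SNPs in the
window — not the mean of per-SNP frequencies, which would weight a 10x
SNP equally with a 200x one. Windows advance in 10-kb steps from position
1 with closed-open spans; empty windows are omitted (not zero-filled).
NAFD = `f_ET - f_ES`; at a QTL, NAFD > 0 means the parent-1 allele
increases the selected-for trait.

### QTL calling (`call_qtls`)

Full intervals are maximal runs of `G' >= threshold`, merged across gaps
under 500 kb. Runs spanning under 500 kb or containing fewer than 50
above-threshold SNPs are reported as minor peaks, never silently dropped,
but not called as QTLs — broad support in both extent and SNP count is
what separates a credible peak from a drift bump. The most-probable
interval operationalizes the visual "shoulder" of a peak as the
contiguous region around the summit with
`G' >= threshold + head_fraction (summit - threshold)`; `head_fraction`
defaults to 0.75 and is exposed, because no numeric shoulder rule exists
in the field — this is a stated convention, not a recovered constant.
The resistant-allele source is the sign of the NAFD window whose centre
is nearest the summit. Optionally (`split_valleys = TRUE`, off by
default because such splits are speculative) an interval containing an
internal valley below the head level with above-threshold peaks on both
sides is split at the valley into two sub-calls — the centromere-divided
double-QTL pattern.

## 3. The synthetic-data generator

`simulate_bsa()` emulates the full design: F3 genotypes by explicit
meiosis, additive phenotypes, tail selection, pooled sequencing.

* **Meiosis.** Crossovers form a Poisson process of rate 1 per Morgan on
  the genetic map (no interference), with a constant physical scale of
  200 kb/cM (rice-like). Adjacent SNPs therefore recombine with the
  Haldane fraction `r = (1 - e^{-2d})/2`. Each F2 is built from two F1
  gametes; each F3 from two gametes of one F2. One F3 offspring per F2
  family is the default (`offspring_per_f2` configurable); marginal F3
  genotype frequencies are (3/8, 1/4, 3/8).
* **Phenotype.** `y = sum_q a_q s_q (g_q - 1) + e`, `s_q = ±1` by the
  configured source parent, `e` normal. When `heritability` is given, the
  residual SD is set from the realized genetic variance so the QTLs
  jointly explain the requested fraction.
* **Selection.** ES = lowest `n_ES` phenotypes, ET = highest `n_ET`; ties
  at either cut break to the lower index, so selection is deterministic.
  Pool sizes must fit inside the configured tail fraction.
* **Sequencing.** Depth per SNP and pool is negative-binomial around the
  pool mean (`depth_dispersion` = NB size, default 10 — moderate
  overdispersion typical of pooled libraries), truncated at 1; the
  parent-1 read count is binomial at the true pool frequency, optionally
  with a symmetric allele-flip error (default 0, since the SNP filters
  assume clean biallelic counts).

Defaults mirror the rice-scale design the package targets: 12
chromosomes summing to ~373 Mb, 10,800 F3 individuals, 4% tails, pools
of 430 (ES) and 385 (ET), mean depths 70x and 89x. The default SNP count
(20,000) is far below a real ~450k-SNP call set; density is configurable,
and all statistics operate per window, so sparser maps mainly cost
interval resolution.

What the generator does **not** emulate: read-level artefacts (mapping
bias toward the reference allele, duplicated reads, indels), genotyping
error, batch structure in phenotyping, dominance and epistasis, and
crossover interference. Passing tests therefore demonstrate correctness
of the statistical machinery under the design's own assumptions, not
robustness to alignment artefacts — on real data the reference-bias shift
of the frequency spectrum (means slightly below 1/2) is visible in
`frequency_summary()` but is reported, not corrected.

## 4. Numerical choices

* **Mode estimation.** The robust fit needs the mode of a continuous G′
  sample; three estimators are provided. `"kde"` (argmax of a Gaussian
  KDE, default bandwidth) has the lowest bias on large samples and is the
  `fit_null()` default. `"logkde"` estimates the density of `ln G'` and
  maximizes the Jacobian-corrected back-transform `f(ln g)/g`; its small
  bandwidth-induced upward bias on `sigma2` (order `h^2`, about 1% at
  n = 10^5) buys structural stability — for log-normal-like data it
  cannot place the mode above the median, which matters on the ~10^3-value
  subsamples inside `estimate_threshold()`, where it is the default.
  `"hsm"` (half-sample mode) is bandwidth-free and maximally robust but
  markedly more variable at these sample sizes.
* **Cancellation-free JSD.** The entropy-difference form of JSD loses all
  precision near null tables (it subtracts nearly equal numbers). The
  implementation uses the per-pool KL form with exact integer frequency
  differences and `log1p`, whose terms are individually nonnegative; the
  identity `2 N JSD = G` then holds to ~1e-13 absolute even at `G ~ 0`,
  and to better than 1e-9 relative wherever G is not itself dominated by
  rounding.
* **Ties and bounds.** Mott segments: leftmost-longest. Summits: leftmost
  maximum. Filter intervals: closed. G′ window membership: closed (edge
  weight is zero anyway). Subsampling bins: anchored at position 1,
  partial final bin kept. BED exports are 0-based half-open; everything
  internal is 1-based inclusive.
* **Degenerate inputs.** Zero-depth SNPs are rejected by the filter, not
  crashed on; zero-SNP chromosomes warn and contribute nothing; an
  all-equal G′ sample is refused by the trimmer (its lower-half spread is
  zero); a left-skewed sample is refused by the fit.

## 5. Validation problem sizes

The statistical acceptance checks run at sizes chosen to exercise the
design faithfully while completing in minutes on one CPU:

* Null error control: 20 genomes, 12 rice-like chromosomes (~373 Mb),
  20,000 SNPs, population 2,000 with 25% tails, pools 430/385, depths
  70x/89x. Selection acts on a pure-noise trait, so the pools are random
  subsets and every significant call is false by construction.
* End-to-end recovery: 100 replicates, same karyotype, 12,000 SNPs,
  population 1,000 with 40% tails, pools 400/400, depth 80x, two QTLs of
  h² = 0.3 each on chromosomes 1 and 5 with opposite source parents.
* Null-fit recovery: 10^5 log-normal draws at the parameters
  (0.9945, 0.3315), clean and with 5% contamination displaced three log
  units upward.

The population sizes are an order of magnitude below the 10,800-seedling
design; this leaves the per-pool composition sampling (which depends on
pool size, not population size) essentially unchanged while keeping the
meiosis simulation fast.

## 6. Known limitations

* **The chi-squared calibration of the per-SNP test ignores pool
  composition.** Two disjoint pools of n individuals differ in their true
  allele frequency with variance ~ `0.75/(2n)` (F3 genotypic variance
  1.5 x binomial); read sampling at depth d adds `~0.5/d`. At pool sizes
  of a few hundred and depths of 70–90x the composition term inflates the
  variance of the pool contrast by roughly 10–15%, which is negligible in
  the bulk of the distribution but material in the far tail where the
  Bonferroni cutoff lives. The genome-wide differential-SNP scan
  therefore runs above its nominal family-wise error rate under a
  faithful simulation of the design — scattered marginal hits outside QTL
  regions are expected, the analogue of the minor peaks at the margin of
  significance that the interval-calling stage deliberately refuses to
  call. The G′ threshold does not suffer from this: its null is estimated
  empirically from the same data and absorbs composition noise.
* **Drift peaks.** For the same reason, broad pool-composition bumps
  occasionally exceed the FDR threshold on QTL-free chromosomes; the
  major/minor classification filters the narrow ones, and occasional
  spurious broad calls are the price of an FDR (rather than FWER)
  criterion on the G′ scan.
* **Low SNP density depresses G′** near chromosome ends and in SNP-poor
  regions (fewer SNPs share the window); no density correction is
  applied.
* The shoulder rule (`head_fraction`) is a convention; real peaks need
  not be self-similar, and the most-probable interval inherits its
  arbitrariness.
* The generator's F3 family structure defaults to one offspring per F2;
  large families (configurable) would add kinship between pool members
  that the analysis, like the original method, ignores.
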