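---
title: "Differential expression without replicates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential expression without replicates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermode)
library(dplyr)
```

## The problem

thermode analyses a specific, awkward experimental design: bulk RNA-seq of
pooled embryos with **one library per condition cell** and no biological
replicates. The motivating design contrasts two turtle species — one with
temperature-dependent sex determination (TSD) and one genotypic (GSD)
species that serves as a negative control — across five developmental
stages (9, 12, 15, 19, 22) and two incubation temperatures (26 °C,
male-producing in the TSD species; 31 °C, female-producing). Each of the
20 libraries is a pool of about ten (TSD) or five (GSD) embryos.

With no replicates, none of the standard dispersion-estimating DE tools
apply as designed. The pipeline implemented here takes the route used for
such data: an exact conditional test on read-count proportions, a very
stringent false-discovery tier to compensate for the unmodelled
between-pool variability, and two independent robustness checks
(normalization-scheme comparison and library subsampling).

## The core statistic

For a focal gene $X$ at one stage in one species, the counts form a 2×2
contingency table:

|                  | 26 °C    | 31 °C    |
|------------------|----------|----------|
| gene $X$         | $n_{11}$ | $n_{12}$ |
| remaining genes  | $n_{21}$ | $n_{22}$ |

The null hypothesis is $\theta = \pi_{11}\pi_{22} / (\pi_{12}\pi_{21}) = 1$:
the gene's *share* of the library is the same at both temperatures.
`fisher_two_sided_p()` computes the exact two-sided p-value by summing,
over all tables with the observed margins, the hypergeometric
probabilities that do not exceed the observed table's probability
(probability-mass convention, with a $1 + 10^{-7}$ relative guard against
floating-point strictness — the same convention as `stats::fisher.test`,
against which the implementation is cross-checked in the test suite, in
addition to an independent enumeration oracle built from binomial
coefficients). Densities that underflow to zero at extreme tables are
clamped to the smallest positive double so p-values stay in $(0, 1]$.

p-values are BH-adjusted **within each species × stage family**
(`bh_adjust()`, a wrapper over `stats::p.adjust`), and genes are assigned
tiers:

* **stringent**: $q \le 10^{-10}$ — deliberately extreme, see below;
* **suggestive**: $q \le 0.05$;
* **ns** otherwise.

Genes with zero (rounded) counts at both temperatures are untestable; they
are reported with $p = q = 1$ and excluded from the BH family so they do
not dilute the correction. Direction of bias compares the two column
proportions exactly (cross-multiplied in double precision); an exact tie is
reported as `none` rather than being assigned arbitrarily.

### Why a $10^{-10}$ tier exists

The Fisher test conditions on the two library totals and therefore models
**sequencing noise only** (multinomial sampling of reads). Real pools of
embryos differ biologically; that variance is invisible to the test and
inflates nominal significance. The acceptance suite demonstrates this as a
monotone property: simulating a null experiment with increasing
negative-binomial dispersion among pools (0, 0.01, 0.05, 0.1) strictly
inflates the suggestive-tier call fraction, while the stringent tier is
what keeps headline calls defensible. This is a documented
anti-conservativeness, not a defect of the implementation.

## Normalization schemes

Four schemes are compared, differing on two axes:

* **UQ100 / UQ99** — upper-quartile scaling: each library's factor is
  proportional to the 75th percentile (linear interpolation, `type = 7`)
  of its *nonzero* counts; `*99` variants first eliminate the top 1
  percentile of genes by mean count (ceiling of the count, lexicographic
  tie-break) from factor estimation **and** from the tested universe.
* **UQHK100 / UQHK99** — the mixed scheme adds housekeeping-gene
  anchoring. The housekeeping factor of a library is the geometric mean,
  over housekeeping genes (defaults `Tfr`, `Hprt1`, constitutively
  expressed in both species), of the gene's count divided by that gene's
  geometric mean across libraries.

All factor vectors are recentred to geometric mean 1 so normalized values
stay near the raw count scale — this matters because the Fisher tests run
on normalized values **rounded half-up** to integers (configurable to raw
counts). Normalization is performed independently per species.

### Why the combined factors are estimated independently

A natural reading of "anchor to housekeeping genes first, then apply
upper-quartile normalization" would re-estimate the upper quartile on the
anchored values. That construction is vacuous: the upper quartile is
scale-equivariant, so the combined factor collapses exactly onto the plain
UQ factor and the mixed scheme would be indistinguishable from UQ100. We
therefore estimate both factors **on the raw counts** and multiply
(`combined = hk_factor × uq_factor`). Two consequences:

* the scheme is genuinely mixed (the two factor components respond to
  different signals: global scale via the quartile, biological scale via
  the anchor genes), and
* the order in which the two factors are applied is *exactly* irrelevant,
  since scalar factors commute — consistent with the empirical observation
  that the order of the two steps does not change the assessment.

Housekeeping anchoring equalizes the housekeeping genes' normalized values
across libraries exactly when the housekeeping counts are proportional to
the libraries' scales and the raw upper quartiles agree; the test suite
constructs such data for the anchoring invariant. On composition-skewed
data the two factor components deliberately disagree — that disagreement
is the point of the comparison.

### What the scheme comparison shows

Because the Fisher table conditions on shares, rescaling a library by a
constant leaves each gene's odds ratio unchanged; what changes is the
*magnitude* of the table entries and hence the test's effective sample
size. A scheme that over-scales a library (because regulated transcripts
dragged its upper quartile) inflates or deflates power wholesale. In the
packaged skew scenario — a large fraction of transcripts strongly
suppressed at the high temperature, housekeeping genes constant — the raw
upper quartile of the high-temperature library under-estimates its
biological scale, UQ100 over-corrects, and the combined scheme (whose
anchor genes are unaffected by the skew) calls **no more** DE genes than
UQ100, reproducing the qualitative ordering that motivates choosing the
combined scheme as the more conservative one.

## Pseudo-replication by subsampling

`partition_counts()` splits one library's counts into $k \in \{2, 3\}$
subsamples. Randomly assigning each read to a subsample with probability
$1/k$ is, at count level, exactly a per-gene multinomial split — drawn here
by sequential binomial thinning, which vectorizes over genes and conserves
every count exactly. Multi-mapping-read effects present in read-level
splitting are out of scope and documented as such.

Matched subsample pairs across the two temperatures are technical
replicates with multinomial noise, so the per-pair test is an **exact
conditional binomial test** (`conditional_binomial_test()`): conditional on
$x_1 + x_2$, the count in subsample 1 is binomial with success probability
$N_1/(N_1+N_2)$; the two-sided p uses the same probability-mass convention
as the Fisher test (the original analysis used dispersion-modelling DE
packages here; with technical subsamples of a single library the exact
conditional test is the appropriate replacement and keeps the statistic
self-contained). `consensus_calls()` BH-adjusts within each pair at 1% FDR
and retains the genes significant **with a consistent direction in every
pair** — an intersection rule, so the consensus set's realized
false-discovery proportion cannot practically exceed a single pair's, at
the price of power.

## The synthetic-data generator

`simulate_experiment()` emulates the study design, not any particular
dataset:

* **Design**: 2 species × 5 stages × 2 temperatures, one pooled library
  per cell; pools of 10 (TSD) and 5 (GSD) embryos.
* **Base means**: log-normal (meanlog 3, sdlog 1.5) relative abundances; a
  configurable fraction (default 5%) shifted 20-fold down to mimic
  ncRNA-like low-abundance transcripts; two housekeeping genes pinned at
  the 80th percentile of the abundance distribution with zero biological
  noise.
* **Effects**: a configurable fraction of thermosensitive genes (default
  5% in the TSD species, 0 in the GSD species — the negative control) with
  log2 fold-change ±2 active during the thermosensitive period (stages 15,
  19, 22); the sign split, abundance multiplier and stage profile are
  configuration knobs (`ts_sign_balance`, `ts_mean_multiplier`,
  `ts_stages`), which is how the composition-skew scenario is built.
* **Noise hierarchy**: each embryo contributes gamma-distributed
  expression with shape $1/\phi$ (so $\phi$ is the usual NB dispersion;
  default 0.05, a stated assumption — the design gives no way to estimate
  it); the pool sums $n$ embryos; sequencing is a single multinomial draw
  of exactly `depth` reads over pooled proportions. Library depth defaults
  to $2 \times 10^6$ reads, a desk-scale stand-in for the tens of millions
  of read pairs of a production library; depth is a knob, and all
  calibration/power claims in the tests are made at the stated sizes
  (20,000 genes, depth $2 \times 10^6$).
* **Truth**: per gene × species × stage log2 fold-change (positive =
  31 °C-biased — the one sign convention used throughout the package), DE
  flag, category tag and base mean, consumed by `evaluate_calls()` for
  realized FDR and stratified power.

What passing tests on this generator do **not** show: robustness to
GC/length bias, isoform switching, mapping artefacts, or real between-pool
biological structure beyond exchangeable gamma noise. The generator is a
calibration instrument, not a claim about turtle biology.

## Numerical and policy choices

* Rounding of normalized values: half-up (`floor(x + 0.5)`), declared
  because rounding conventions differ and the tests assert it.
* Quantile convention: linear interpolation between order statistics
  (R `type = 7`), on nonzero counts only.
* Trimming: global ranking by mean raw count across the libraries being
  normalized; `ceiling(fraction × n_genes)` genes with a small numeric
  slack so exact multiples are not inflated by floating-point
  representation; lexicographic tie-break at the boundary.
* Fisher two-sided convention: probability-mass method; the doubled
  one-tail alternative differs slightly on asymmetric tables and was not
  chosen — the convention is declared rather than inferred.
* FDR family: per species × stage, matching how the tests are performed;
  pooling across stages would mix exchangeable families of very different
  signal density.
* Power-panel convention: "adequately expressed" strong effects are genes
  with at least 50 expected reads in the **weaker** of the two temperature
  libraries; a 4-fold-down gene with 12 expected reads at 31 °C is
  information-limited for any exact test at this depth, and no
  implementation could recover it.
* log2 fold-changes are reported with pseudo-count 0.5 on the normalized
  per-temperature values; they are descriptive only and never used in
  testing.
* Direction concordance against an external (e.g. qPCR) profile is the
  fraction of matching directions over stages where **both** profiles are
  significant and non-tied; stages where either side is `ns` are excluded
  from the denominator by default (agreeing on "no signal" is not evidence
  of concordant direction; `include_ns = TRUE` restores the permissive
  reading). This replaces a qualitative visual comparison with a
  reproducible surrogate and is labelled as such.
* Cross-species comparison takes the shared gene universe (or a
  two-column orthology mapping) as caller input; no orthology inference.

## Problem sizes used by the packaged checks

The test suite runs the calibration and power checks at 20,000 genes and
depth $2 \times 10^6$ (the full two-species design for the null
calibration; one species for the dispersion sweep and the power panel),
the scheme comparison at 2,000 genes × depth $2 \times 10^5$, and the
pipeline determinism check at 600 genes. `scripts/acceptance.R` recomputes
the same quantities from scratch at the same sizes.

## Known limitations

* Significance from a single pooled contrast is evidence of *suggestive*
  differential expression; the stringent tier controls the testable
  (sequencing) noise only. This mirrors the analysis the pipeline
  reimplements and is stated prominently in the outputs' documentation.
* The subsample consensus inherits the source library's biological
  idiosyncrasies: subsamples are technical replicates, so consensus
  calling cannot rescue the missing biological replication either.
* Between-species normalization is intentionally absent (each species is
  normalized alone); cross-species comparisons are set-level only.
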