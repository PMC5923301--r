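---
title: "Compositional divergence analysis of venom-gland transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional divergence analysis of venom-gland transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomcomp)
```

## The problem

Rattlesnake venoms fall into a well-known dichotomy: Type A venoms are
neurotoxic, dominated by the heterodimeric phospholipase A2 called Mojave
toxin (an acidic subunit, MTXA, and a basic subunit, MTXB), while Type B
venoms are hemorrhagic, rich in snake venom metalloproteinases (SVMPs) and
C-type lectins (CTLs). venomcomp implements an analysis pipeline for
comparing bulk venom-gland transcriptomes between the two phenotypes:

1. decide which toxin transcripts are *present* in each individual from
   read coverage;
2. treat per-individual TPM abundances as compositional data, replace
   zeros, and apply the centered log-ratio (clr) transform;
3. test each toxin for expression divergence in every Type A x Type B pair
   of individuals against an empirical null built from nontoxin
   transcripts; and
4. summarize toxin-family composition and compare per-individual toxin
   counts between venom types with a rank-sum test.

The package ships the printed tables of a nine-individual Mojave
rattlesnake (*Crotalus scutulatus*) study — five Type A and four Type B
venom glands — as plain-text fixtures (`scutulatus_samples()`,
`scutulatus_toxins()`, `scutulatus_presence()`, `scutulatus_pla2()`), and a
synthetic-data generator so every downstream stage can be tested without
any sequence data.

## Presence calling

A transcript is present in a sample when at least 90% of its positions
have read depth of at least 5x (`call_presence()`, parameters
`min_depth = 5`, `min_covered_fraction = 0.90`). The rule is stated in the
negative in the source study — a transcript with *more than* 10% of its
sequence under 5x is absent — so a transcript with exactly 90% of
positions at 5x is present; the boundary is tested explicitly. Presence is
deliberately independent of the TPM value: multi-mapping reads can give a
transcript nonzero estimated abundance even when it is not in the
transcriptome, which is the reason a coverage rule is needed at all.

## Compositional handling

TPM values sum to 1e6 per sample, so they carry only relative information.
All cross-sample comparisons therefore run on log-ratios.

**Zero replacement.** Log-ratios need strictly positive parts.
`replace_zeros()` uses simple multiplicative replacement: each zero in a
row becomes a small value $\delta$ and the nonzero parts are scaled by
$1 - \sum\delta/\mathrm{total}$, which preserves the row total and leaves
every ratio among observed parts untouched. The source study names a
zero-replacement routine but not its method or parameters, so the choice
here is the package's own: by default $\delta$ is 0.65 x the smallest
positive value of the row, a common convention for continuous
compositions. Both the method and $\delta$ are configurable and recorded
in the output's `zero_replacement` attribute, and the test suite exercises
sensitivity of the invariants (total preservation, ratio preservation) to
these settings. Because downstream outlier counts depend on $\delta$ when
a toxin is absent on one side of a comparison, counts such as the
per-toxin pair tallies should be read as properties of this configuration,
not as universal constants.

**clr transform.** For a strictly positive row $x$,
$\mathrm{clr}_i = \ln x_i - \frac{1}{D}\sum_j \ln x_j$. Rows sum to zero,
rank order within a row is preserved, and the result is invariant to
rescaling a row by a positive constant (both properties are tested). The
geometric mean is taken over the full transcript set supplied — toxins and
nontoxins together when both are available, toxins only when only the
packaged toxin table is loaded — and the subset size is recorded in the
`clr_subset_n` attribute.

**Type averages.** `average_type_individual()` appends an "average A" /
"average B" pseudo-individual as the arithmetic per-transcript mean of TPM
values. The pipeline order is fixed: average on the TPM scale first, then
replace zeros, then transform. Averaging after replacement would leak the
$\delta$ values of individual samples into the pseudo-individual.

## The divergence test

For one pair of individuals $(i, j)$, the null distribution of expression
divergence is the set of absolute clr differences of the nontoxin
transcripts, $\{|\mathrm{clr}_i(k) - \mathrm{clr}_j(k)|\}$. Nontoxins are
presumed not to diverge systematically between venom types, so the width
of this distribution measures technical plus neutral biological noise. The
threshold is its 99th percentile (`null_threshold()`), computed with the
linear-interpolation percentile definition (the common default in
scientific computing; the inverse-ECDF order statistic is available by
flag, and the choice is recorded). A toxin is an outlier when its absolute
clr difference is *strictly* greater than the threshold — a tie at the
threshold is not "outside" — with direction given by the sign
(`flag_outliers()`).

`aggregate_pairs()` repeats this for every (A, B) pair — 20 comparisons
under the packaged 5 x 4 design — and reports, per toxin, the number of
pairs in which it was up in the B member (`UpB`) and up in the A member
(`UpA`), plus `delta = UpB - UpA`, mirroring the study's outlier table
layout. Spearman, Pearson, and $R^2$ statistics are computed per pair,
separately for the toxin and nontoxin subsets; a combined value is not
reported because the two subsets answer different questions.

An OLS variant (`ols_band_outliers()`) fits ordinary least squares of
$\mathrm{clr}_j$ on $\mathrm{clr}_i$ through the nontoxins and flags
toxins outside a 99% interval around the line, matching the
scatterplot-style display of such analyses. Whether that display's band is
a prediction interval or a mean-confidence band is ambiguous in the
source; the package implements a **prediction interval** (a confidence
band around the fitted mean shrinks with the number of nontoxins and
would flag nearly every point at n ~ 1900) and labels it as such. The
absolute-difference percentile rule remains the primary method and the
only one used for pair aggregation; the two methods are tested to agree on
direction for every toxin both flag.

## Rank-sum comparison of toxin counts

`mann_whitney()` compares per-individual toxin counts between venom types.
The statistic is the Mann–Whitney U for the first group,
$W = \#\{(a,b): a > b\} + \tfrac12\#\{(a,b): a = b\}$. The exact p-value
enumerates all $\binom{n_1+n_2}{n_1}$ group labelings (a permutation test,
valid with ties by explicit request); the default for tied data is the
normal approximation with tie-corrected variance and continuity
correction, the convention that reproduces the study's printed p = 0.019
on its tied counts. The test is implemented in the package rather than
wrapped from `stats::wilcox.test` because the base exact path refuses
ties; `wilcox.test` serves as an independent oracle in the test suite.

Two caveats are documented rather than hidden. First, published summaries
of this test sometimes quote a "df"; a rank-sum test has no degrees of
freedom, and the result object echoes `df_echo = n1 + n2 - 2` purely for
comparability. Second, the corrected normal approximation can undershoot
the exact p-value at small sizes: enumerating every untied configuration
with $n_1+n_2 \le 10$, the worst exact-minus-approximate gap is ~0.088 at
$n_1=n_2=2$ and ~0.03 at the 4 x 5 design; the suite asserts these
measured bounds rather than a blanket claim.

## The synthetic-data generator

`simulation_config()` / `simulate_venom_data()` produce datasets with the
statistical structure the analysis assumes, defaulting to the packaged
study's conditions: 5 Type A + 4 Type B samples, 1889 nontoxins, and 75
toxins in the study's 17-family catalog shape.

* **Expression** is log-normal on the TPM simplex: per-transcript base
  abundance on the natural-log scale (default mean 6, sd 2 — TPM spanning
  roughly 1 to 1e5, as in the packaged toxin table), per-sample noise with
  sd `within_type_sd` (default 0.7), then closure to 1e6. Count-level
  (negative binomial) noise is deliberately not modeled: the pipeline's
  entry point is TPM, and counts enter only through coverage.
* **Presence structure** comes from per-family blocks: `A_only`,
  `B_only`, `shared`, or `mixed` (per-sample Bernoulli presence).
  Transcripts in exclusive blocks get `exclusive_base_bonus` (default 2
  natural-log units) added to their base abundance, because
  venom-type-defining toxins are among the most highly expressed
  transcripts in real glands, not a random draw from the abundance
  distribution. The saturated-block property (a B-exclusive block scoring
  UpB = 20, UpA = 0 across all pairs) is exercised with a bonus of 4,
  i.e. block members comparable to the major toxins of the packaged
  table.
* **Spiked effects** are natural-log shifts added to Type B samples for
  chosen transcripts; they are expression shifts, not presence changes, so
  spiked transcripts are forced present everywhere. With shifts at 4 x the
  null width ($2.576\sqrt{2}\,\sigma_w$), the divergence stage recovers
  spiked toxins with >= 95% sensitivity across all 20 pairs.
* **Coverage** is per-base Poisson with mean scaled by relative abundance
  (mean `depth_mean` for an average-abundance present transcript), floored
  at 5.5 for truth-present transcripts so the presence rule can be
  exercised. Note a Poisson mean of 5.5 covers only ~62% of positions at
  >= 5x, so low-abundance present transcripts are still — realistically —
  missed by the 5x/90% rule; presence sensitivity is reported, not assumed
  to be 1. Absent transcripts get a contiguous zero-depth stretch
  (`dropout_fraction_absent` of the length) and sub-threshold depth
  elsewhere. Coverage is generated for toxins by default; simulating
  per-base depth for 1889 nontoxins x 9 samples would be millions of draws
  with no consumer.
* **Calibration.** `simulate_null_data()` draws toxins and nontoxins from
  the same distribution; `estimate_null_flag_rate()` then measures the
  per-pair flag rate. With a 99th-percentile null built from n = 1000
  nontoxins the expected rate is slightly above 1% (the chance of a new
  draw exceeding the ~990th order statistic is about 11/1001); Monte-Carlo
  runs with 200 replicates land at 1.1–1.3%.

What the generator does **not** emulate: read-level sampling (FASTQ),
mapping ambiguity among paralogs, assembly artifacts, and count-level
overdispersion. Passing tests on synthetic data therefore validate the
pipeline's statistics under its stated model, not the upstream
bioinformatics.

A fixed integer seed drives every draw; the same configuration and seed
reproduce a dataset bit for bit.

## Inconsistencies in the packaged tables

Two internal inconsistencies of the source tables surfaced while packaging
and are preserved, not silently repaired:

* The printed per-individual "toxins present" row says 66 for CLP1835, but
  the printed presence matrix for that individual sums to 64.
  `count_toxins_present()` reports the matrix sums;
  `scutulatus_reported_counts()` returns the printed row. The rank-sum
  result of `run_paper_analysis()` uses the reported counts (the study's
  test input, giving W = 0, p = 0.019); the matrix-count version is
  returned alongside (`ranksum_from_matrix`, p = 0.017).
* The study quotes a Type A mean toxin count of 48.6 ± 6.1; both the
  printed counts row and the matrix give 48.2. The package reports the
  recomputed means.

## Problem sizes and numerical choices

The test suite and the acceptance script run the synthetic benchmarks at
moderate sizes chosen to make the Monte-Carlo answers stable while keeping
a full run fast on a single core: 500 nontoxins for the block-saturation
and recovery checks, 1000 nontoxins x 75 toxins x 200 replicates for null
calibration, and 100 random instances per oracle-equivalence check.
Degenerate inputs fail fast with informative errors before any sampling:
empty groups, all-zero compositions, nonpositive lengths, unlabeled
samples, replacement deltas at or above the smallest observed value, and
zero-variance OLS fits. Correlations on zero-variance vectors are reported
as `NA` (undefined), never coerced to 0.

## Limitations

The pipeline consumes abundance tables; it does not run read mapping or
RSEM, and expected counts are an input, not an output. The empirical-null
test is pairwise and unadjusted for multiple comparisons, as in the source
design — the per-toxin pair counts are descriptive tallies, not
family-wise error-controlled calls. Toxin-only clr (when no nontoxin
table is available) changes the geometric mean and therefore absolute clr
values; comparisons remain internally consistent but are not numerically
interchangeable with full-transcriptome clr.
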