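---
title: "Methods: cross-pipeline concordance of tractometry sex differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-pipeline concordance of tractometry sex differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractconcord)
```

## The problem

Tractography offers many equally defensible processing pipelines — different
diffusion models, streamline reconstruction strategies and bundle
segmentation algorithms — and these can produce visibly different
reconstructions of the same white-matter pathway. The question this package
operationalizes is whether such pipeline choices change the *scientific
conclusions* drawn downstream. The concrete setting is a classic group
contrast: sex differences in per-bundle microstructural and volumetric
features, measured on the same subjects by two independent pipelines.

The unit of analysis is the tract-feature pair. With the default registries
— 49 bundles shared between a whole-brain-tractogram atlas segmentation and
TractSeg bundle-specific tractography, and 9 features (AD, FA, MD, RD from
DTI; NDI, ODI, ISOWF from NODDI; tract volume and TBV-normalized volume) —
there are 49 × 9 = 441 pairs, splitting into 49 × 7 = 343 microstructural
and 49 × 2 = 98 volumetric comparisons. Everything upstream of the
tract-feature table (model fitting, tractography, segmentation, feature
extraction) is out of scope: the package starts at two long-format tables.

## Per-pipeline effect statistics

For each pair, the sex difference is tested with a pooled-variance
(Student's) two-sample t-test, male minus female, two-sided, with
`df = n_M + n_F - 2`. Student's rather than Welch's test is the default
because the downstream agreement analysis is defined in terms of the
pooled-SD effect size; the two share a scale, and the algebraic identity

$$ t = \frac{d}{\sqrt{1/n_M + 1/n_F}} $$

ties every t statistic to its Cohen's
$d = (\bar{x}_M - \bar{x}_F) / s_p$. The identity is asserted (to 1e-10)
on every batch of results as a structural self-check.

Magnitude bins on $|d|$ are the conventional negligible / small / medium /
large cut-offs at 0.2, 0.5, 0.8. The published convention leaves the
boundary values ambiguous; here the bins are half-open —
$[0, 0.2), [0.2, 0.5), [0.5, 0.8), [0.8, \infty)$ — so the partition has no
gaps or overlaps and $d = 0.2$ is "small".

Multiplicity is controlled by Bonferroni over the family actually tested:
the default threshold is `alpha_family / m` with `m` the number of pairs in
the batch (0.05/441 ≈ 1.1e-4 for the full roster). `m` is exposed rather
than hard-coded because the family size is a modeling decision — a
replication of an earlier analysis may inherit a *more* conservative
threshold from a larger original family, which is why
`significance_policy(override_threshold = 6.5e-5)` exists and is used as
the reference setting throughout this package's examples.

Degenerate pairs — a group with fewer than two subjects after dropping
missing measurements, or zero pooled variance — are flagged and carried as
non-significant `NA` rows rather than aborting the batch; zero pooled
variance is deliberately an error at the single-test level (it is not the
same thing as $d = 0$).

## The agreement taxonomy

Two pipelines' results for the same pair are classified on the lattice
(both / one / neither significant) × (same / opposite direction), giving
six exhaustive base categories:

| category | significant | direction |
|---|---|---|
| A | both | same |
| B | one | same |
| C | neither | same |
| D | neither | opposite |
| E | one | opposite |
| F | both | opposite |

The four reported composite levels are defined on top: strict agreement =
A ∪ C ∪ D; soft agreement = A ∪ B ∪ C ∪ D; strict disagreement = F; soft
disagreement = D ∪ E ∪ F. Category D — neither result significant but the
point estimates pointing opposite ways — belongs to strict agreement
(neither pipeline claims an effect) *and* soft disagreement (the
directions differ). Keeping the six-category partition as the primitive
and defining the composites on top preserves both readings; the D count is
reported explicitly, and it is why soft agreement and soft disagreement
can sum above 100%.

Two genuinely open choices were settled as follows. First, whether soft
agreement should include category D: the variant including D is the
default (it keeps soft agreement a superset of strict agreement, which is
the only reading under which a soft-agreement rate can exceed the strict
rate on the same data); the directional-only variant (A ∪ B ∪ C) is
available via `soft_agreement = "directional_only"`. Second, a direction
of exactly "none" ($d = 0$, a measure-zero event on continuous data) is
treated as compatible with either direction — the pair is classified
same-direction, and the number of such pairs is recorded in the
`n_direction_none` attribute rather than silently absorbed.

Percentages are `100 · count / stratum size`, rounded half-up at one
decimal by default. A truncation option exists because proportions near a
rounding boundary (e.g. 8/98 = 8.16%) are sometimes reported truncated
(8.1%) rather than rounded; the convention used is always recorded in the
summary object.

## Bootstrap sensitivity comparison

Whether one pipeline is systematically *more sensitive* — larger $|d|$ for
the same pair — is judged with a nonparametric bootstrap of
$\Delta = |d_1| - |d_2|$. The resampling unit is the subject: each
replicate draws subjects with replacement, stratified by sex so the
design's group sizes $n_M, n_F$ are preserved, and each drawn subject
carries their measurement from *both* pipelines, preserving the
within-subject pairing that makes the two $d$ estimates positively
correlated. Breaking that pairing demonstrably widens the interval (it is
a property test in the suite), which is the statistical reason the paired
design has power here. The 95% interval is the 2.5% and 97.5% empirical
quantiles with linear interpolation (`stats::quantile` type 7), fixed for
reproducibility; BCa-style corrections are deliberately not used — the
percentile interval is the minimal-assumption default and its calibration
is verified by simulation instead. A pipeline is flagged when the interval
excludes zero. No multiplicity correction is applied across the 441
intervals; the tally of flags per feature and per method is the intended
summary, not a family of confirmatory tests.

The default is 10,000 iterations; the test suite and the acceptance script
use 1,000–2,000, which changes quantile Monte-Carlo error by a few
thousandths — immaterial at the tolerances checked. Degenerate replicates
(zero pooled variance in a resample) are redrawn with a cap and counted; an
unstratified variant and a signed-difference statistic ($d_1 - d_2$) are
available behind flags.

## The synthetic cohort generator

The generator exists so that every stage is testable against known truth.
Per subject $i$, tract $t$, feature $f$, on the standardized scale:

$$ s^{(k)}_{itf} = d^{(k)}_{tf}\,\mathbf{1}[i \text{ male}]
   + \sqrt{\rho}\,U_{itf} + \sqrt{1-\rho}\,E^{(k)}_{itf}, $$

with standard normal $U$ (shared between pipelines) and $E^{(k)}$
(pipeline-specific), all independent. Within each sex the variance is
exactly 1, so the population Cohen's d in pipeline $k$ is exactly
$d^{(k)}_{tf}$, and the within-sex correlation between pipelines is exactly
$\rho$ — effects are injected on the standardized scale precisely so these
hold by construction rather than approximately. Values are then mapped to
feature-native units by per-feature affine transforms (e.g. FA around 0.50
± 0.03, MD around 0.75e-3 ± 0.04e-3 mm²/s, volume around 15,000 ± 3,000
mm³), which exist purely so generated files look plausible; no downstream
statistic can see them.

Defaults mirror the motivating cohort: 575 women and 490 men (1,065
subjects), the 49-tract and 9-feature registries, females higher on FA and
males higher on the remaining features. Two values are modeling choices
with no external anchor: $\rho = 0.6$ (a moderate correlation — two
pipelines reading the same anatomy through different noise; no empirical
between-pipeline correlation was available to calibrate it) and the
auto-drawn effect profile, per-(tract, feature) base magnitude uniform on
(0, 0.6) with per-pipeline jitter of SD 0.05, folded positive so the sign
convention is exact. That profile encodes "small-to-medium effects, mostly
concordant between pipelines"; pairs with near-zero base magnitude still
produce occasional direction flips between pipelines, which is what
exercises the soft-disagreement categories.

RNG discipline: one master seed spawns a deterministic substream per
(tract, feature) via a polynomial label hash (all arithmetic exact in
doubles, reduced modulo a prime below 2³¹), so adding a feature or
reordering the roster never perturbs existing draws; the per-pair
bootstrap seeds are derived the same way, making `run_sensitivity` results
independent of pair order.

What the generator does *not* emulate: heavy-tailed or heteroskedastic
noise, missing-data mechanisms, spatial correlation between neighboring
tracts, age or TBV covariate structure, and any systematic (mean-shift)
bias between pipelines. Passing tests therefore certify the statistical
machinery under Gaussian, complete, exchangeable-subject conditions — not
robustness of the t-test family to real tractometry distributions.

## Verification: problem sizes and what is checked

The suite checks, among others: exact hand-derived t and d on a textbook
case; agreement of t, d and p with independent oracles (`stats::t.test`
and a direct formula evaluation) to 1e-9 on 1,000 random small samples;
type-I error within binomial 3σ of α = 0.05 over 2,000 null pairs
(n = 30/sex); power monotone over true d ∈ {0, 0.1, 0.2, 0.3} with 500
replicates per point (n = 200/sex); recovery of d = 0.5 within 0.05 on
average over 200 replicates at cohort scale (490/575); 95% percentile-CI
coverage of a known Δ|d| = 0.2 within 95 ± 4 points and a false-flag rate
within binomial 3σ of 5% (200 outer replicates, 2,000 bootstrap iterations,
n = 1,065); exhaustive enumeration of the taxonomy; and bit-identical
reproducibility from seeds throughout. These sizes were chosen so each
property is tested at meaningful power while the whole suite stays quick
to run; they are stated here so that reported tolerances can be read
against the Monte-Carlo error they imply.

## Known limitations

* The package tests mean differences only; covariate adjustment (age, TBV),
  mixed models and FDR-style alternatives to Bonferroni are out of scope.
* Agreement is counted on raw proportions, with no chance correction
  (no kappa): two pipelines with many true null pairs will show high
  strict agreement by construction.
* The bootstrap compares magnitudes per pair; pooling tracts within a
  feature, or correcting the 441 intervals for multiplicity, is left to
  the user's judgment.
* Missing measurements are dropped pairwise (per tract-feature), which
  assumes missingness unrelated to the measurement; the effective n per
  pair is reported so users can audit this.
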