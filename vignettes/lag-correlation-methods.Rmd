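---
title: "Methods: Gini correlation and developmental lag models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gini correlation and developmental lag models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginilag)
```

## The problem

Grass stems lignify as they mature: phenylpropanoid pathway transcription
rises during elongation, and lignin and wall-bound hydroxycinnamic acids
(*p*-coumaric acid, pCA; ferulic acid, FA) accumulate in the wall, while
enzymatic digestibility (ED, the sugar yield of a cellulase digestion)
falls. A natural systems question is one of *timing*: does expression of
the biosynthesis genes track wall composition in the same sample, or
does it precede deposition? With only a handful of genotypes, a short
ordered developmental series, and three biological replicates, the
practical instrument is correlation between expression at one series
position and trait values (or trait changes) at the same or a later
position, with a statistic that is robust at small n.

`ginilag` implements that analysis end to end: the Gini correlation
coefficient with permutation tests and FDR q-values, the lag-model
datasets, sign-based expected/unexpected classification with
precision–recall scoring, a significant-correlation network exporter,
efficiency-adjusted ΔCq conversion for qPCR inputs, and the supporting
group statistics (one-way ANOVA, Tukey–Kramer with compact letters,
PCA). A synthetic generator with known ground truth stands in for
measured data in all tests.

## The Gini correlation coefficient

For paired vectors the directed coefficient is

$$GCC(x \mid y) \;=\; \frac{\sum_i \left(2\,r_i(y) - n - 1\right)
x_i}{\sum_i \left(2 i - n - 1\right) x_{(i)}},$$

where $r_i(y)$ is the rank of $y_i$ and $x_{(i)}$ the order statistics
of $x$. The numerator weighs the *values* of one variable by the
*ranks* of the other; the denominator is the same sum under perfect
agreement, so the statistic lies in $[-1, 1]$, reaches the bounds
exactly for co-/anti-monotone pairs, and is invariant to strictly
increasing transforms of $y$ and positive affine transforms of $x$.
This rank/value hybrid keeps more information than Spearman while
tolerating outliers and non-linear monotone relations better than
Pearson; `correlate_all()` reports Pearson and Spearman alongside as
cross-checks.

Numerical choices:

* **Ties.** Tie-averaged ranks replace the integer weights in the
  numerator, which removes any dependence on input order. With tied
  values the bounds are attained only up to floating-point summation
  order (about 1e-15), which is why tests of exact bounds use tie-free
  data.
* **Symmetrization.** The two directed values rarely coincide. One
  coefficient per pair is reported: the directed value of larger
  magnitude, ties broken toward $GCC(x \mid y)$, with the direction
  recorded. This is a package convention, chosen because the magnitude
  is what the permutation test thresholds; both directed values stay in
  every record.
* **Exact summation order.** Numerator and denominator iterate in
  x-ascending order so that perfectly monotone pairs return exactly
  ±1.

## Permutation p-values and q-values

The null of no association is simulated by permuting $y$. For $n \le 6$
all $n!$ permutations are enumerated (the p-value is then exact, with
floor $1/n!$ from the identity permutation); otherwise $B = 2000$ Monte
Carlo permutations are drawn and the add-one estimate
$p = (1 + \#\{|GCC^*_b| \ge |GCC|\})/(B + 1)$ is used, which avoids
$p = 0$ and keeps the FDR machinery valid. The permutation loop runs in
C++ and draws from R's RNG, so every record is reproducible from a
seed; per-record sub-seeds are derived by hashing the variable-pair
names, which makes results independent of evaluation order.

q-values are Storey-style, $q = \pi_0 \cdot \text{BH}$. The $\pi_0$
spline estimate over a $\lambda$ grid is unstable for the small
families this analysis produces (one model family is 11 genes × 6
outcomes = 66 tests), so below 50 tests the estimate is pinned at
$\pi_0 = 1$, making the q-values exactly the Benjamini–Hochberg step-up
values. Each model family is corrected separately — model comparison
tables score families independently, so a joint correction across
models would double-penalize.

## Lag models

Let $N$ index the ordered pseudo-time series (whole-tiller stages
V3 < E4 < R3, or segments of the elongation tiller S3 < S2 < S1, both
young → old). Three families of gene-expression (GE) versus cell-wall
(CW) datasets are built:

* **Concurrent** (`N vs N`): GE and CW from the identical sample.
* **Delta** (`N vs Δ(N+k − N)`): GE at $N$ against the *change* in a
  trait from $N$ to $N+k$, $k \ge 1$; tests whether expression precedes
  deposition. $k = 0$ is rejected as degenerate (all-zero outcomes).
* **Cumulative** (`N vs N+k` levels, or fixed selectors such as segment
  S1 expression against whole-tiller R3 composition): GE at one
  position against the accumulated trait level later.

Cross-position rows are matched by (genotype, replicate) by default.
The replicate index refers to clonal biological replicates that persist
across the series, so within-replicate pairing preserves sample size;
a `by_genotype_mean` option collapses replicates first for designs
where replicate identity does not persist. Pooled by-replicate row
counts obey $G \cdot R \cdot (T - k)$.

One documented ambiguity: in a segment series, "later in the series"
means *more mature* tissue under the S3 → S2 → S1 encoding, but the
reversed reading (top-of-tiller first) also occurs in practice. Rather
than choosing silently, `model_spec(direction = "old_to_young")` runs
the reversed pairing explicitly.

Significance conventions follow the field's practice for these two
families: $q < 0.05$ for change-score (delta) models and $q < 0.01$ for
level (concurrent/cumulative) models and the trait–trait network; both
are per-model-configurable.

## Expected/unexpected scoring

Phenylpropanoid-derived components (lignin, pCA, FA) are expected to
correlate *positively* with pathway expression, digestibility
*negatively*. `classify_records()` labels each significant record
accordingly; `score_model()` reports precision (expected over all
significant; undefined and rendered "−" when nothing is significant)
and recall (expected over the testable gene × outcome pairs, e.g.
11 × 6 = 66). `model_table()` sorts by precision with undefined values
last, ties broken by expected count then name.

For parameter-recovery studies on synthetic data,
`score_against_truth()` restricts scoring to the outcomes whose
expected sign the generator actually encodes — lignin, pCA, and the
three ED variables. The concurrent-tracking trait FA is excluded there
by design: when expression follows a mid-series pulse, the *change* in
a concurrent trait is mechanically anti-correlated with its level, so
its lagged-model sign is a construction artifact, not a recoverable
parameter. (Full-panel scoring with the field sign rule remains the
default everywhere else.)

## The synthetic generator

`sim_config()` encodes the study conditions the analysis assumes: 3
genotypes × 3 replicates × 3 ordered positions, 11 pathway transcripts,
6 traits. Its structural commitments, chosen once:

* **Expression pulse.** Every gene shares one unimodal profile peaking
  mid-series, scaled per gene (geometric spread 0.5–2×) and per
  genotype; defaults give a peak ~2× the earliest and ~3× the latest
  position on the geometric-mean scale, matching the fold contrasts
  typical of elongation-stage maxima. One genotype (the upland-like
  VS16 stand-in) carries a lower scale, which lets tests reproduce the
  genotype-convergence pattern qualitatively.
* **Lagged deposition.** Lignin and pCA accumulate the pathway-mean
  expression from `lag` positions earlier:
  $L(t) = L_0 + \kappa \sum_{\tau \le t - d} \bar g(\tau)$, so the
  increment at $t$ reflects expression at $t - d$. The cumulative-sum
  form is an assumption — no quantitative deposition kinetics are
  established for this system — and is the simplest structure
  consistent with delayed accumulation. The gain κ is shared across
  genotypes: a genotype-specific gain would destroy the exact
  noiseless collinearity between expression and trait increments that
  the oracle tests rely on, so genotype differences enter through the
  expression scale instead.
* **Concurrent trait.** FA is an increasing affine function of current
  pathway-mean expression.
* **Digestibility.** ED at three digestion times declines linearly in
  accumulated lignin and pCA, truncated at zero; baselines are set so
  truncation never binds at the defaults.
* **Noise.** Multiplicative mean-one lognormal noise with coefficient
  of variation `noise_cv` (default 0.2): compositional and qPCR
  measurements are positive with roughly constant CV. `noise_cv = 0`
  makes the generator an exact closed-form oracle for every downstream
  statistic.

What the generator does *not* emulate: absolute concentrations,
trait-specific noise structure, monosaccharide biology (optional
columns are white noise), replicate-level biological covariance, or
series of unequal length per genotype. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
structure, not fidelity to any particular measured dataset.

## Group statistics

`anova_oneway()` is the classical equal-variance F test over
genotype × position cells (the one-way, cell-level design matches the
shared letter sets seen in composition tables; nothing in the package
assumes nested factors). `tukey_hsd()` evaluates all pairwise
comparisons from the studentized range distribution with Tukey–Kramer
standard errors, and `compact_letters()` implements insert-and-absorb
letter assignment with alphabetic ordering; every output is verified
post hoc against its p matrix and an inconsistency is an error.
`pca_traits()` wraps `princomp`; the correlation matrix is the default
because the trait panel mixes units (µg/mg vs assay yields), with
covariance mode available, and the per-component sign is fixed by
making the largest-magnitude loading positive.

## qPCR conversion

Technical replicates are averaged on the Cq scale (cycle noise is
approximately additive), then
$R = E_{ref}^{Cq_{ref}} / E_{gene}^{Cq_{gene}}$ with per-amplicon
amplification factors ($1 < E \le 2$) supplied as inputs — efficiency
estimation from fluorescence curves is a separate concern delegated to
dedicated tools. Per-plate efficiency variants are not modeled.

## Problem sizes and determinism

The test suite and the acceptance script run everything at the design's
own scale: 27-sample series, 66-test families, $B = 2000$ permutations,
50-seed recovery studies, 1000-draw calibration checks. All randomness
flows from a single seed through hashed sub-seeds (kept below $2^{31}$),
so reruns are byte-identical. The recovery comparison counts a
concurrent model with no significant records as outperformed whenever
the delay model detects true structure with positive precision — a
model that finds nothing provides no evidence of the lag.

## Known limitations

* The symmetrization rule and the tie policy are package conventions;
  other implementations of the Gini correlation may choose differently,
  so coefficients are comparable across tools only up to those
  choices.
* Storey's $\pi_0$ on 66-test families is noisy; the BH fallback below
  50 tests is deliberately conservative. On *signal-dense* families —
  the synthetic panel can make nearly every gene–outcome pair non-null —
  the $\pi_0$ estimate legitimately collapses toward its floor $1/m$
  and weakly-estimated records then pass the q cutoff; this is Storey's
  estimator working as designed (there are almost no true nulls to
  protect), but it means q-based screening is a weaker sign filter on
  such families than on sparse ones.
* Series with more than a few positions would invite genuine
  time-series modeling (smoothing, autoregression); the package stops
  at position pairing by design.
* Precision/recall scoring treats every gene–outcome pair as equally
  possible; it does not model correlation between tests within a
  family.
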