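---
title: "Discovering single-miRNA regulation of whole pathways"
author: "miRPathLink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering single-miRNA regulation of whole pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRPathLink)
```

## The question and the model

A single microRNA that represses several genes of the same curated pathway
can act as a master switch for that pathway's function. miRPathLink tests
this idea in four stages: (1) build an evidence set of miRNA–gene pairs
supported by multiple prediction tools; (2) for every pathway pick the one
miRNA with the most targets inside it and score the overlap with a
hypergeometric tail statistic, correcting across pathways with Storey
q-values; (3) check that the signal is specific to curated gene sets by
rerunning the whole selection on randomized pathways; (4) tie the
association to phenotype through probabilistic pathway-activity scores,
group stratification, survival splits and group-wise differential
correlation.

### The enrichment statistic

With `M` genes tested overall, a pathway of `N` genes, a miRNA with `K`
supported targets among the `M`, and `x` of those targets inside the
pathway, the score is the hypergeometric tail

$$p \;=\; 1 - \sum_{i=0}^{x}
  \frac{\binom{K}{i}\binom{M-K}{N-i}}{\binom{M}{N}}
  \;=\; P(X > x).$$

Note the convention: the sum runs through `x` itself, so the statistic is
the probability of *strictly more* than `x` hits — one term smaller than
the conventional enrichment tail $P(X \ge x)$. The two differ by roughly
an order of magnitude in the interesting regime (at `x = 6, K = 124,
N = 13, M = 1460` the strict tail is $3.0\times10^{-5}$, the conventional
tail $3.5\times10^{-4}$). `hypergeomTail()` implements the strict
convention as its default and offers `tail = "geq"` for users who expect
the conventional one. Numerically the complement is summed directly over
the upper tail in log space; the naive `1 - cdf` form cancels to exactly 0
once the tail drops below machine precision, which matters because
best-miRNA selection routinely produces p-values near $10^{-40}$.

Because the tested miRNA is chosen as the maximizer of `x`, the p-value is
post-selection and optimistically biased; the randomized-pathway null
(below) is what anchors the procedure, since the same selection is applied
to the random sets. Ties in `x` are broken by the smaller p-value and then
lexicographic miRNA id, so the selection is deterministic and
order-invariant.

### Multiple testing

`storeyQvalues()` estimates the null proportion $\pi_0$ on the grid
$\lambda = 0.05, 0.10, \dots, 0.95$ via
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$, smooths the grid
with a cubic polynomial evaluated at $\lambda = 0.95$, and clips to
$(0, 1]$. q-values are the usual step-up
$q_{(i)} = \hat\pi_0\,\min_{j\ge i} m\,p_{(j)}/j$; with $\pi_0$ fixed at 1
this is exactly Benjamini–Hochberg, which the test suite uses as an
independent oracle. Pathways that no miRNA targets at all are reported but
excluded from the FDR computation — their tail probability is near 1 by
construction and carries no information.

### The randomized-pathway null

`nullDistribution()` rebuilds "pathways" by sampling gene sets of random
size 4–50 from the pool of genes that belong to any observed pathway and
reruns best-miRNA selection and FDR within each iteration (the reference
analysis uses 1000 iterations; scaled-down runs use fewer). The universe
size `M` stays at the observed value: the random sets are drawn from the
same pool of tested genes, so the number of genes tested does not change.
`compareObservedVsNull()` contrasts observed and pooled null q-values with
a Welch t-test.

A calibration caveat, verified empirically by the test suite: the
q-values inside one run are jointly computed (shared $\hat\pi_0$, shared
step-up rescaling, shared prediction matrix), so they are not independent
draws, and the pooled two-sample t-test is anticonservative when there is
truly no signal — in repeated no-signal simulations it rejects at the 5%
level roughly 20% of the time, not 5%. With planted regulation the
separation is so extreme (t-statistics beyond 25, p below $10^{-90}$) that
this miscalibration is irrelevant for detection, but the comparison p-value
should be read as descriptive, not as a calibrated test. Per-iteration
median q-values are exposed (`iterationMedianQ()`) for summaries that
respect the iteration structure.

### Pathway activity

The phenotype analyses need a per-sample, per-pathway activity score in
$[0,1]$ computed from expression. The package implements a transparent
probabilistic model in the spirit of interaction-likelihood activity
tools: each gene's expression across samples is modelled as a
two-component Gaussian mixture fitted by EM, and `p_up(g, s)` is the
posterior that gene `g` is in its higher-mean component in sample `s`. An
interaction with promoter set $P$ and inhibitor set $I$ then occurs with
likelihood $\prod_{g\in P} p_{up}(g,s)\,\prod_{g\in I}(1-p_{up}(g,s))$,
and a pathway's activity is the mean over its interactions (or, without
interaction annotation, the mean of `p_up` over its genes). This is a
fully specified surrogate for that family of methods, not a bit-level
clone of any particular tool; users needing exact parity with a specific
implementation should treat the scores as comparable in semantics, not in
value.

Numerical choices, all deterministic: components initialize at the 25th
and 75th percentiles with a shared variance of a quarter of the gene
variance; the variance is floored at $10^{-4}$ times the gene variance;
convergence is a parameter change below $10^{-8}$, capped at 500
iterations; all genes iterate together on a shrinking active set.
Constant genes get `p_up = 0.5` and a `degenerate` flag; below 8 samples
the mixture is unidentifiable in practice and the fit degrades to the same
flat state with a warning. Interactions referencing unmeasured genes are
skipped; a pathway with more than half of its interactions skipped is
flagged `low_coverage`, and a pathway with no measurable gene yields `NaN`
and is excluded downstream.

### Phenotype linkage

`activityGroupTest()` is a Welch two-sample t-test (robust to unequal
variances, asymptotically equivalent to the pooled test) on a pathway's
activity between two groups; `scanStratification()` applies it across
pathways and attaches Storey q-values. `survivalSplitTest()` splits
samples at the median activity — the split rule is a package choice, made
explicit here — and compares Kaplan–Meier curves with the log-rank test.
`groupCorrelation()` computes Pearson (optionally Spearman) correlation
per group and contrasts the two coefficients with Fisher's z,

$$z = \frac{\operatorname{atanh} r_1 - \operatorname{atanh} r_2}
  {\sqrt{1/(n_1-3) + 1/(n_2-3)}},$$

turning "correlated in one group, uncorrelated in the other" — the broken
control signature — into an assertable claim with a p-value. Reporting the
per-group coefficients alone is common practice; the formal contrast is
this package's design choice, so that the signature can be tested rather
than eyeballed.

## What the synthetic generator emulates

`generateScenario()` produces a complete seeded study: 100 pathways of
size 4–50 over a universe of 1500 genes, 300 miRNAs, an 8-tool prediction
table, bimodal mRNA expression (modes 3 SD apart, noise SD 1), miRNA
expression, a two-group phenotype of 100 samples each, and exponential
survival (group-A median 1000 days, hazard ratio 3 for group B, censoring
at 3000 days). These defaults are the package's reference conditions.

Planting, in the default configuration:

* every pathway gets a planted miRNA targeting half of its genes with
  two-tool support, mirroring the empirical situation in which essentially
  all curated pathways carry a dominant miRNA;
* planted miRNAs additionally receive 30–90 out-of-pathway targets. This
  keeps `K` realistically large relative to `x` (real miRNAs target on
  the order of a hundred genes across a universe of ~1500); without it, a
  planted miRNA occasionally has *all* its targets inside its own pathway,
  and the strict tail then returns exactly 0 — an artifact, not a signal;
* one primary pathway takes the maximum size (50) and a planted fraction
  of 0.8, so the ground-truth top association is unambiguous across seeds;
* only the primary pathway carries the expression-level signals: a
  group-A activity shift of 2 SD on its genes, and a latent-factor
  (Gaussian copula-style) correlation of $\rho = -0.6$ between the primary
  miRNA and its planted targets in group A only, with half the targets
  flipped to $+0.6$ to mirror the sign mix seen in real target sets.

Background predictions enter each (miRNA, gene) cell independently with
probability 0.01, with 1/2/3-tool support drawn at probabilities
0.50/0.35/0.15, so about half of the background pairs survive the
two-tool filter.

What the generator does *not* emulate: count-based sequencing noise, batch
effects, probe-level normalization, correlated pathway membership, or real
pathway topology. Passing tests therefore demonstrate that the pipeline
recovers the structures it assumes, at realistic sizes — not that those
structures are the ones generating any particular real data set.

Problem sizes used by the test suite (chosen to exercise the method at
meaningful scale while keeping a full run comfortable on one core): 50
repetitions for separation and stratification checks, 200 for null
calibration, 100 seeds for correlation recovery, 50 null iterations per
repetition, and 10,000 simulations for the type-I error of the Fisher-z
contrast.

## Known limitations

* The best-miRNA p-value is post-selection; only the randomized-pathway
  comparison, which repeats the selection, is selection-aware.
* The pooled observed-vs-null Welch test is anticonservative under the
  null (see above); treat its p-value as descriptive.
* The activity model is a surrogate: two-component Gaussian mixtures and
  an interaction-product likelihood, averaged per pathway. Pathways whose
  regulation is not captured by promoter/inhibitor products (e.g. strong
  OR-logic redundancy) will be summarized bluntly.
* `M` counts distinct genes across pathways under analysis, whether or not
  they are anyone's predicted target or present on an expression platform;
  analyses that must condition `M` on measured genes should subset the
  pathway database first.
* Identifiers are opaque case-sensitive strings; symbol/alias mapping is
  curation and happens upstream of this package.

## A worked miniature

```{r example, eval = FALSE}
cfg <- scenarioConfig(seed = 7)
bundle <- generateScenario(cfg)
dir <- tempfile(); writeBundle(bundle, dir)

pairs <- restrictToUniverse(filterMinTools(bundle@predictions, 2),
                            bundle@pathways)
assoc <- associateAll(bundle@pathways, pairs)
head(rankAssociations(assoc), 3)

nd <- nullDistribution(pairs, nPathways = 100, nIterations = 50, seed = 1)
compareObservedVsNull(associations(assoc)$q_value, pooledNullQ(nd))

states <- fitGeneStates(bundle@mrna)
act <- pathwayActivity(bundle@pathways, states)
scanStratification(act, bundle@phenotypes, "A", "B")
```

The README shows the same run end-to-end through `runPipeline()` with the
numbers it prints.
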