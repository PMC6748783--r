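---
title: "Which distribution fits replicated RNA-seq counts, and what the wrong choice costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Which distribution fits replicated RNA-seq counts, and what the wrong choice costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countgof)
```

## The two questions

Differential-expression tools work with two to three biological replicates
only because they assume a parametric form for the cross-replicate
variability of each gene's read count. `countgof` addresses the two
questions that assumption raises:

1. **Goodness of fit.** Given a highly replicated single-condition count
   matrix, which of four candidate models — normal, log-normal, Poisson,
   negative binomial (NB) — is compatible with each gene's counts across
   replicates? (`gof_battery()`)
2. **Cost of the wrong model.** If a two-group test assumes one of these
   distributions, how often does it call differential expression between
   two groups drawn from the *same* condition, where every call is a false
   positive by construction? (`run_fp_experiment()`)

Everything runs on synthetic matrices from `simulate_null_matrix()`, so
the full pipeline is testable on one CPU in minutes.

## The goodness-of-fit battery

Each gene's counts $x_1, \dots, x_n$ across $n$ replicates are tested
against the four models; raw p-values are Benjamini–Hochberg adjusted
*within* each distribution across the genes actually tested for it, and a
gene rejects a model when the adjusted p-value falls below
$\alpha = 0.05$. Summaries report the rejected fraction over tested genes,
with excluded and degenerate genes counted separately — mixing them into
the denominator would understate rejection rates for the models that
exclude many genes.

**Normal.** The D'Agostino–Pearson omnibus statistic
$K^2 = Z_1^2 + Z_2^2$, combining the z-transforms of sample skewness
(D'Agostino) and kurtosis (Anscombe–Glynn), referred to $\chi^2_2$. The
kurtosis transform is unstable in very small samples, so the test requires
`n_min = 8` replicates; below that a gene gets status `too_few`. A known
property worth stating: the $\chi^2_2$ reference is slightly liberal at
moderate $n$ (at $n = 16$ the true null rejection rate at nominal 0.05 is
about 0.057), which is inherent to the approximation, not to this
implementation. For the exactly symmetric case ($g_1 = 0$) the skewness
z-score is taken as 0, its mathematically correct value.

**Log-normal.** The same test applied to $\log x_i$. The log of zero is
undefined, so any gene with a zero count is excluded (`excluded_zeroes`)
rather than imputed — with shallow or noisy data this can remove a
substantial minority of genes, and the summary reports how many.

**Poisson.** The dispersion index $D = \sum_i (x_i - \bar x)^2 / \bar x$
referred to the upper tail of $\chi^2_{n-1}$. A binned
observed-vs-expected $\chi^2$ is a possible alternative construction; the
dispersion index was chosen because it is exact in its conditional
derivation, has no binning tuning, and is the classical test for
overdispersion — the failure mode of interest here.

**Negative binomial.** The NB probability generating function
$G(t) = (p/(1-(1-p)t))^r$ satisfies the differential identity
$(1-(1-p)t)\,G'(t) = r(1-p)\,G(t)$. With the empirical PGF
$G_n(t) = n^{-1}\sum_j t^{x_j}$ and moment estimates $\hat r, \hat p$,
the statistic integrates the squared defect of this identity:

$$T_n = n \int_0^1 \left[(1-(1-\hat p)t)\,G_n'(t) -
\hat r(1-\hat p)\,G_n(t)\right]^2 t^a \, dt .$$

Choices behind this implementation:

* **Moment estimation.** $\hat r = \bar x^2/(s^2 - \bar x)$,
  $\hat p = \bar x / s^2$ — closed-form and cheap enough to re-estimate
  inside every bootstrap replicate, which the test requires for correct
  calibration. When $s^2 \le \bar x$ the moment fit does not exist; the
  gene is reported `degenerate` and excluded from the NB denominator
  rather than assigned p = 1 (assigning 1 would silently count
  underdispersed genes as NB-compatible). On Poisson-like data roughly
  half of genes land there, which the Poisson test covers.
* **Weight and quadrature.** $a = 5$ damps the region near $t = 1$, where
  $G_n'$ grows like $x_{\max} t^{x_{\max}-1}$ for large counts and would
  otherwise dominate the integral; the integral is evaluated by fixed
  64-point Gauss–Legendre quadrature on $[0,1]$, which is effectively
  exact for these smooth integrands. Both are configurable in
  `nb_gof_config()`.
* **Bootstrap.** The null law of $T_n$ is unknown, so p-values come from a
  parametric bootstrap from NB$(\hat r, \hat p)$ with the +1 correction
  $p = (1 + \#\{T_b \ge T_{obs}\})/(B+1)$, giving the floor $1/(B+1)$ —
  about $10^{-3}$ at the default $B = 1000$ and about $10^{-7}$ at
  $B = 10^7$, at linearly proportional cost. Bootstrap replicates whose own
  moment fit is degenerate are evaluated in the Poisson limit of the
  statistic ($(1-\hat p) \to 0$, $\hat r(1-\hat p) \to \bar x$), which is
  the continuous continuation of the same defect and keeps the bootstrap
  distribution well defined.

```{r gof-example, eval = FALSE}
spec <- synthetic_spec(n_genes = 1000, n_samples = 16,
                       silent_fraction = 0, phi0 = 0.2, phi1 = 0, seed = 1)
cm <- simulate_null_matrix(spec)
gt <- gof_battery(cm, nb_gof_config(n_bootstrap = 500, seed = 1))
summary(gt)
```

On NB-simulated data this reproduces the characteristic ordering seen in
deeply replicated real experiments: the Poisson model is rejected almost
everywhere, the normal model for a sizable minority, the log-normal for a
few percent, and the NB essentially nowhere.

## The synthetic generator

`synthetic_spec()` describes one condition measured in $n$ replicates:

* A **silent class** (default fraction $\approx 0.18$, mirroring the
  ~6000-of-33,851 annotated-but-undetected genes of a well-annotated plant
  transcriptome) with true mean zero.
* Expressed genes draw means $\mu_g$ **log-uniformly** on `mean_range`
  (default $[10, 1000]$) — a flat coverage of the two decades where the
  distribution tests actually discriminate; real transcriptomes have
  heavier extremes in both directions, but those genes are either
  excluded (zeroes) or trivially accepted/rejected by every model.
* Counts are **gamma–Poisson**: $X_{gj} \sim$ NB with mean $s_j\mu_g$ and
  variance $s_j\mu_g + \phi(\mu_g)(s_j\mu_g)^2$, so $\phi \to 0$ recovers
  the Poisson limit explicitly. The dispersion trend
  $\phi(\mu) = \phi_0 + \phi_1/\mu$ (defaults $\phi_0 = 0.05$,
  $\phi_1 = 2$) has the standard decreasing shape; the defaults are
  documented placeholders for a typical bulk experiment, not estimates of
  any particular dataset, and every study-level run in this package states
  its $\phi$ explicitly (usually a constant 0.2).
* **Library-size factors** $s_j$ default to mild lognormal variation
  (sd 0.15 on the log scale, geometric mean 1), the depth spread typical
  of libraries sequenced together.
* **Contamination** adds i.i.d. Poisson background to every cell —
  the simplest model of a low uniform read carpet from genomic DNA
  carry-over, whose visible effect is silent genes appearing lowly
  expressed. `corrupt_outlier()` instead degrades one replicate with
  per-gene lognormal multiplicative noise, reproducing the
  poorly-correlating-replicate phenotype that `flag_outliers()` detects.

What the generator deliberately does **not** emulate: gene–gene
correlation, isoform structure, positional/GC bias, batch effects beyond a
single corrupted column, and read-level artifacts. Passing tests therefore
demonstrate that the statistics behave as designed when their model
assumptions hold (and fail in the designed directions when violated) — not
that any particular real dataset satisfies those assumptions.

## Quality control

* `correlation_matrix()` computes pairwise Pearson correlation across all
  genes on $\log(\text{count} + 1)$ by default — the standard concordance
  scale; `log = FALSE` gives the raw-count alternative since the scale
  used by any particular published heatmap is often unstated.
* `flag_outliers()` flags replicates whose *median* off-diagonal
  correlation falls below 0.95 — a threshold sitting in the wide gap
  between a degraded replicate (R of roughly 0.83–0.87) and healthy ones
  (R > 0.99); it is configurable because that gap is dataset-dependent.
* `downsample()` equalises depth by drawing a multivariate hypergeometric
  subsample per column: column sums hit the target exactly and every cell
  is bounded by its original value. This is the count-level analogue of
  down-sampling read pairs and realigning; it cannot reproduce
  alignment-level effects of true read-level down-sampling and is
  documented as that approximation.

## Minimal distribution-matched callers

Each caller isolates one distributional assumption with the simplest
defensible two-group test, because the point of the mock comparison is to
attribute false-positive behaviour to the assumed distribution rather
than to any tool's engineering:

* `nb_exact_caller()` — NB conditional exact test on group sums scaled to
  a common effective library (sizes $n_g/\phi$; $\phi = 0$ reduces to the
  conditional binomial). A single common dispersion is used — enough for
  false-positive behaviour and it keeps the test exactly enumerable.
* `lognormal_caller()` — moderated pooled t-test on
  $\log(\text{scaled count} + 0.5)$, per-gene variances shrunk toward the
  grand mean with `n_prior = 4` pseudo-samples (0 disables moderation).
* `poisson_caller()` — pools counts within groups and tests the group-A
  pool against a binomial at the effective-depth share, deliberately
  ignoring biological overdispersion.
* `binomial_caller()` — Fisher's exact test per gene on the 2×2 table of
  gene count vs rest-of-library in each pooled group, on raw counts with
  no normalisation (mirroring the tool class it represents).
* `rank_caller()` — Mann–Whitney with Poisson down-sampling to the
  minimum effective depth, U averaged over 20 thinnings, p from the exact
  rank-statistic null at the nearest achievable value. At 3 vs 3 the
  smallest achievable two-sided p is 0.1, so no gene can pass FDR < 0.05
  on its own — a structural property, not a bug.

Conventions shared by all callers: effective depth is the median-of-ratios
size factor (geometric mean 1) — counts are scaled by the factor alone,
since it already captures relative depth; two-sided p-values sum all
outcome probabilities not exceeding the observed outcome's probability
(the exact-test lineage convention, matching `binom.test` and
`fisher.test`); a gene is tested iff its pooled count over both groups is
positive (no fold-change or abundance filter); q-values are BH within the
tested genes.

Two fine points. The Poisson thinning in `rank_caller()` draws columns in
sorted-sample-id order, which makes the caller exactly label-symmetric;
and its "identical groups give p = 1" idealisation holds exactly only
when effective depths are equal (no thinning) — with unequal depths the
caller's own resampling noise can leave p slightly below 1. Second, the
binomial and Poisson callers are nearly the same procedure at sequencing
depths (the hypergeometric converges to the binomial when the library
dwarfs the gene), so their false-positive fractions track each other
closely; the large gaps between the corresponding published tools come
from tool internals these minimal designs intentionally strip away.

## The mock-comparison harness

`run_fp_experiment()` draws, for each replicate number `nr` and
iteration, two disjoint sets of `nr` samples uniformly from the pool
(by default all samples minus flagged outliers), runs every caller on the
*same* split — a paired design, so caller contrasts are free of sampling
noise — and records the per-iteration false-positive fraction
significant/tested. That per-iteration fraction is the primary
statistic; a per-gene recurrence table (`gene_recurrence()`) is kept as a
supplementary view for asking whether the same genes recur across
iterations. Splits are drawn without replacement within an iteration and
independently across iterations, so distinct iterations may overlap.
`summarize_fp()` reports median, quartiles and 2.5%/97.5% limits using
the type-7 linear-interpolation convention of `stats::quantile()`
(stated because order-statistic conventions differ), with outliers
defined as points beyond the 95% limits.

The whole experiment is bit-reproducible from `seed`: splits, thinnings
and bootstraps all flow from it.

## Numerical choices

* Analytic p-values are floored at the smallest positive double so that
  extreme statistics never produce p = 0 (BH requires p in (0, 1]).
* The exact-test engine enumerates each gene's support on a window of
  mean ± 8 sd (+20), always extended to include the observed value;
  out-of-window mass (≤ ~1e-13, all in the tails for a unimodal pmf) is
  counted as extreme, so truncation can only perturb a p-value far below
  any decision threshold. Log-pmfs are evaluated from shared lgamma
  lookup tables in compiled code; probability ties with the observed
  outcome are recognised up to a relative 1e-7, the same factor
  `fisher.test` uses.
* Down-sampling draws sequential conditional hypergeometrics, which is
  the exact multivariate hypergeometric factorisation.

## Problem sizes

Defaults are chosen so a laptop-scale run completes in minutes: the NB
bootstrap defaults to $B = 1000$ (the test suite uses 500), calibration
suites use 10,000 genes (1,000 for the bootstrap test), and the shipped
false-positive experiment uses 10,000 genes × 16 replicates × 50
iterations for nr = 3…7. The constructions scale linearly in $B$, genes
and iterations for users who want publication-depth runs (e.g.
`--bootstrap` at $10^7$-scale for a $10^{-7}$ p-value floor).

## Known limitations

* The NB test's power depends on the undocumented weight $a$; different
  choices reweight which departures from NB are detected.
* Degenerate-fit genes are excluded from the NB denominator; a
  likelihood-based NB test without that exclusion is out of scope.
* The callers model one normalisation (median-of-ratios) — differences
  between published tools' internal normalisations are not reproduced.
* Correlation-based outlier flagging assumes most replicates are healthy;
  it will not resolve two simultaneously degraded replicates that
  correlate with each other.
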