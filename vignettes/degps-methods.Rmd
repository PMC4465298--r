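---
title: "Methods: GP normalization and pooled-permutation DE testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GP normalization and pooled-permutation DE testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degps)
```

## The model

Within one RNA-Seq library, the read count of a transcript is modeled by a
generalized Poisson (GP) distribution with parameters $(\theta, \lambda)$:

$$\Pr(X = x) = \frac{\theta(\theta + x\lambda)^{x-1}
  e^{-\theta - x\lambda}}{x!}, \qquad x = 0, 1, 2, \dots$$

with $\theta > 0$ and $\max(-1, -\theta/q) \le \lambda \le 1$; when
$\lambda < 0$ the support is truncated at $q$, the largest integer with
$\theta + q\lambda > 0$ (pairs implying $q < 4$ are rejected). The mean is
$\theta(1-\lambda)^{-1}$ and the variance $\theta(1-\lambda)^{-3}$, so
$\lambda$ is a pure overdispersion dial: $\lambda = 0$ is Poisson, and the
variance-to-mean ratio $(1-\lambda)^{-2}$ grows without bound as
$\lambda \to 1$. $\theta$ plays the role of a depth parameter — the
intensity of the underlying counting process before dispersion inflates it.

On realistic data (abundances spanning several decades), the fitted
$\hat\lambda$ sits far from zero — often above 0.9 — which is the empirical
motivation for not using the raw sample mean as a depth factor.

### Fitting

The $\lambda$ MLE solves the estimating equation

$$\sum_{i=1}^n \frac{X_i(X_i - 1)}{\bar X + (X_i - \bar X)\hat\lambda}
  - n\bar X = 0, \qquad \hat\theta = \bar X(1 - \hat\lambda).$$

An important caveat for anyone comparing implementations: this equation is
sometimes reproduced with a sign slip as $\sum X_i(1 - X_i)/(\cdot)$, whose
left side is nonpositive for counts $\ge 1$ and therefore admits no root.
The form above is the one consistent with maximum likelihood and with
$\hat\theta = \bar X(1-\hat\lambda)$; `fit_gp_mle()` implements it,
aggregated over unique count values for speed.

Numerical choices: the root is bracketed over
$(\lambda_{lo} + 10^{-6},\, 1 - 10^{-6})$, where $\lambda_{lo}$ keeps all
denominators positive ($\lambda > -\bar X/(X_{max} - \bar X)$) and the
truncated support valid; `uniroot` runs at absolute tolerance $10^{-8}$.
If no sign change is bracketed — underdispersed or otherwise boundary data —
the fitter falls back to bounded profile-likelihood maximization
(`optimize` with $\theta$ profiled as $\bar X(1-\lambda)$), and
$\hat\lambda$ is capped at $1 - 10^{-6}$ so the implied moments stay
finite. All-zero or zero-variance samples are rejected with an error
instructing the caller to filter; the pipeline's `filter_all_zero()`
removes transcripts with no reads in any compared sample before fitting,
since such rows carry no information and only destabilize $\hat\lambda$.

The pmf is evaluated in log space ($x!$ via `lgamma`, the power factor as
$(x-1)\log(\theta + x\lambda)$), so counts of order $10^5$ are safe.
For $\lambda < 0$ the truncated pmf mass over $0..q$ sums to slightly less
than one; `pgp()` renormalizes by that total so the CDF reaches exactly 1
at $q$ — GP-Quantile normalization requires a proper CDF. Random variates
use the exact branching (Lagrangian) representation for
$0 \le \lambda < 1$ and inversion of the renormalized table for
$\lambda < 0$.

## Normalization

* **GP-Theta** divides each sample by $\hat\theta = \bar X(1-\hat\lambda)$,
  i.e. the sample mean *shrunk* by the fitted overdispersion. Unlike the
  raw mean (global scaling), a handful of extremely abundant transcripts
  cannot dominate the factor, because their effect is absorbed into
  $\hat\lambda$.
* **GP-Quantile** replaces each count $x$ by the fitted probability
  $P(X < x)$, putting every sample on the common scale $[0, 1)$. The
  strict convention $P(X < x)$ is the default; $P(X \le x)$ and the
  mid-probability $P(X<x) + \tfrac12 P(X = x)$ are available via the
  `lower` argument of `pgp()` / `normalize_gp_quantile()` for users who
  prefer a smoother transform. Probabilities are passed to the test as-is,
  with no normal-scores transform.
* Comparators: **global** scaling (to the grand mean column total — the
  target is arbitrary and cancels in the scale-free T statistic),
  **quantile** normalization (average-rank tie handling, matching limma's),
  **TMM** (published defaults: 30 % M-trim, 5 % A-trim, inverse-variance
  weights, reference = column with upper quartile closest to the mean;
  verified against edgeR to within 2 %), and **lowess** MA-trend removal
  against a geometric-mean pseudo-reference on $\log_2(x+1)$ (span 0.4,
  3 robustness iterations — unstated upstream, chosen to match common
  microarray practice and exposed as arguments).

## Testing

Per transcript, the Welch statistic
$T = (\bar x - \bar y)/\sqrt{s_x^2/n_x + s_y^2/n_y}$ is computed on the
normalized values. The null distribution is built by recomputing $T$ for
every transcript under every group-label reassignment and pooling all
statistics into one flat empirical distribution. Design choices, each
switchable:

* **Permutation universe.** Distinct assignments of $n_A$ of the $n$
  samples to group A — $\binom{n}{n_A}$ of them; the identity assignment
  is excluded by default (it only re-adds the observed statistics and
  biases small exhaustive nulls; `include_identity = TRUE` restores it).
  All assignments are enumerated when $\binom{n}{n_A} \le$ `max_perms`
  (default 1000, covering the 252 assignments of a 5 + 5 design);
  otherwise a seeded without-replacement sample is drawn.
* **Two-sided p-values with the add-one convention**,
  $p_g = (1 + \#\{|s| \ge |t_g|\})/(1 + N)$: sidedness is not dictated by
  the method's description, but its own simulations create both up- and
  down-shifts, so $|T|$ is the natural choice; add-one keeps $p > 0$,
  which BH requires.
* **Tie tolerance.** The complement of the observed assignment is in the
  pool with statistic exactly $-t_g$, so every transcript has a structural
  tie at $|t_g|$. Tail counting therefore treats pooled values within
  relative distance $10^{-8}$ of $|t_g|$ as ties. This makes p-values
  bitwise invariant under rescaling of the normalized matrix and
  independent of floating-point evaluation order; accidental non-structural
  ties at that tolerance have probability ~0 for continuous data.
* **Undefined statistics** (both group variances zero) contribute nothing:
  they are excluded from the pool and counted (`n_dropped`), and such
  observed transcripts get $p = 1$. Treating them as 0 would distort the
  pooled null.
* **Regularized T** (`statistic = "regularized-t"`): group variances are
  shrunk toward their across-transcript median with a James–Stein-style
  weight $w = \min(1, \sum 2s_g^4/(n-1) / \sum (s_g^2 - \mathrm{med})^2)$.
  This follows the cited variance-shrinkage idea; exact numerical agreement
  with any particular shrinkage-t package is not claimed, and the tests
  assert only the limiting cases and rank agreement with ordinary T.
* The raw pooled statistics are exposed (`result$null$pooled_stats`) so
  external FDR machinery (e.g. density-based local FDR tools) can consume
  them; BH on the empirical p-values is the primary procedure.

The permutation engine is vectorized (two matrix products per null), so no
worker pool is needed; a `--workers` flag is accepted by the CLI for
interface compatibility and results are identical for any value.

## The simulators: what they emulate, and what they do not

`simulate_nb_counts()` draws per-transcript baseline means from a
log-normal profile ($\log_{10}\mu \sim N(2, 1)$, i.e. typical abundances of
10–10⁴ reads spanning ~5 decades) and NB dispersions from
$\mathrm{Uniform}(0.1, 0.6)$, the range typical of bulk RNA-Seq estimates;
a `de_fraction` of transcripts has its mean multiplied by `effect_size`
(default 3, a moderate fold change) in one group, half up / half down by
default; with probability `outlier_prob` an entry is multiplied by a
$\mathrm{Uniform}(5, 10)$ factor — the standard convention for "abnormally
high" single-entry outliers. `make_source_matrix()` +
`resample_null()` / `apply_shift()` / `apply_scale_shift()` reproduce the
resampling-style evaluation: null groups drawn from one population, then
additive shifts ("varied quantities" are drawn Normal($m$, $m/5$),
truncated at zero and rounded — the minimal reading of "variation as one
fifth of the value"; a uniform law with the same moments is switchable)
and multiplicative scaling on top.

What a green simulation test establishes: calibration (type I error,
FDR) and robustness *under NB marginals with independent transcripts*.
What it does not: correlation between transcripts, library-preparation
batch structure, zero inflation beyond NB, or the heavier-than-NB tails of
real data — the GP model's main target. Power numbers from these defaults
are deliberately conservative (median TPR of a few percent at 5 + 5 and
fold change 3): the bound-style acceptance checks concern error control,
not absolute power, and the effect-size grid is exposed for power curves.

## Metrics

Type I error is the sub-$\alpha$ fraction of nominal p-values under a null
scenario (defined only there). FDR is the truly-non-DE fraction of
adjusted-p calls, 0 for an empty call set (the conventional choice);
TPR the called fraction of true DE. Partial AUC integrates the step ROC
over FPR $\in [0, 0.05]$ by trapezoid, with tie blocks contributing single
diagonal segments (equal to averaging over tie-consistent orderings);
both the raw and the $1/\mathrm{fpr}_{max}$-normalized value are
available, normalized being the default reported. Nominal p-values are the
ranking score (any per-method monotone transform, like BH, leaves pAUC
unchanged).

## Known limitations

* Two-group designs only; no covariates, pairing, or multi-group layouts.
* Gene/transcript-level counts only — no position-level modeling.
* The GP fit is per sample across transcripts; samples whose counts are
  all equal (zero variance) cannot be fitted and must be filtered.
* Underdispersed samples ($\hat\lambda < 0$) are handled (truncated
  support, renormalized CDF) but are not the intended regime; RNA-Seq
  libraries are essentially always overdispersed.
* Exhaustive enumeration is limited by `max_perms`; for large designs the
  sampled null is seeded but no longer permutation-exact.
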