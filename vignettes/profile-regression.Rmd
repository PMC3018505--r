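---
title: "Profile regression for case-control exposure data: model, sampler and design choices"
author: "profilereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Epidemiological studies of multifactorial diseases routinely face a moderate
number of correlated, individually weak categorical risk factors. Standard
regression struggles here: examining all interactions inflates the parameter
count, model selection becomes unstable, and collinearity muddies
interpretation. Profile regression sidesteps this by changing the unit of
inference from individual coefficients to the *exposure profile* — the vector
$x_i = (x_{i1}, \dots, x_{iP})$ of a subject's categorical/ordinal covariate
values — and asking which profiles cluster together and how those clusters
relate to disease.

## The model

The model has two submodels fitted jointly.

**Assignment submodel.** Subjects belong to latent clusters indexed by an
allocation variable $z_i = k$. Within cluster $k$, covariate $p$ takes value
$x$ with probability $\phi_k^p(x)$; the $\phi_k^p(\cdot)$ jointly define the
cluster's prototypical profile. Nominal covariates get an unrestricted
probability vector with a Dirichlet$(1,\dots,1)$ prior. Ordinal covariates
use an ordered-threshold probit construction: strictly increasing thresholds
$\lambda_1 < \dots < \lambda_{M-1}$ on a standard normal scale induce
$\phi(j) = \Phi(\lambda_{j+1}) - \Phi(\lambda_j)$. This respects only the
*order* of the categories — any interior point of the simplex is reachable —
while letting the posterior shift mass smoothly along the scale.

**Disease submodel.** Each cluster carries an association parameter
$\theta_k$ with $P(y_i = 1) = \theta_k$ for its members (plain mode). With
confounders $w_i$, a logistic formulation
$\mathrm{logit}\,P(y_i=1) = \beta w_i + \theta_k$ is used instead, and
$\theta_k$ becomes the baseline log-odds at the confounder reference value
zero. A prospective likelihood is used even for case-control data; with
categorical exposures and noninformative priors this does not distort the
association parameters of interest.

Because both submodels are fitted as one unit, disease status informs
cluster membership and vice versa.

The number of clusters is not fixed. The mixture is a Dirichlet process,
represented by truncated stick-breaking: $v_k \sim \mathrm{Beta}(1,\alpha)$,
$w_k = v_k \prod_{j<k}(1 - v_j)$, with a configurable truncation level
(default 50) and a Gamma$(2,1)$ hyperprior on the concentration $\alpha$.
The sampler reports when posterior mass at the truncation tail exceeds
$10^{-4}$, the signal to raise the level.

## Priors and tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| nominal $\phi_k^p$ prior | Dirichlet$(1,\dots,1)$ | noninformative |
| ordinal threshold prior | uniform on induced probabilities | density $\propto \prod_j \varphi(\lambda_j)$ in threshold space |
| plain $\theta_k$ prior | Beta$(1,1)$ | conjugate |
| logistic $\theta_k$, $\beta_q$ priors | Normal$(0, 10^2)$ | weakly informative on log-odds; prevents separation blow-ups; config-exposed because no canonical value exists |
| $\alpha$ hyperprior | Gamma$(2, 1)$ | config-exposed |
| truncation | 50 | tail mass monitored |
| iterations / burn-in / thin | 30000 / 10000 / 10 | sized so a ~800 x 9 problem runs in minutes on one CPU |
| threshold / $\theta$ / $\beta$ proposal scales | 0.25 / 0.4 / 0.1 | adapted during burn-in, frozen after |

There is no canonical choice of prior or move for cluster-specific ordered
thresholds, so both are this package's own design: the
prior on thresholds is the pushforward of the uniform distribution on the
induced category probabilities (whose Jacobian gives the
$\prod_j \varphi(\lambda_j)$ density), and the move is random-walk
Metropolis on one interior threshold at a time, rejected when it breaks the
ordering. This choice keeps the construction testable: at $M = 2$ the model
is a reparameterised Bernoulli and the sampled $\Phi(\lambda_1)$ must match
the Beta conjugate posterior exactly, which the test suite verifies by
Kolmogorov–Smirnov distance.

## The sweep

Each MCMC iteration updates, in order: allocations (categorical draws via
the Gumbel-max trick over `weight x profile likelihood x outcome
likelihood`, vectorised across subjects and cluster slots); stick weights
(Beta full conditionals) and $\alpha$ (its conditional under truncated
stick-breaking is a Gamma, so an exact draw is used rather than a Metropolis
step); cluster profile parameters (Dirichlet conjugate draws for nominal,
threshold Metropolis for ordinal — empty clusters draw from the prior, which
is what lets the occupied count grow); disease parameters (Beta conjugate in
plain mode, Metropolis in logistic mode); and finally missing covariate
entries, each redrawn from its current cluster's category distribution
$\phi_{z_i}^p(\cdot)$, i.e. imputation is part of the joint posterior
simulation rather than a preprocessing step. Rows with a missing *outcome*
are instead dropped at load time, and missing confounders are not imputed
(the model ties imputation to cluster structure, which confounders do not
have); such rows are dropped with a warning.

Joint correctness of the sweep is checked by a successive-conditional
(Geweke-style) test at small scale ($n = 10$, $P = 2$): alternating one
Gibbs sweep with regeneration of the data given the parameters must
reproduce the moments of forward simulation from the prior, on
label-invariant functionals.

## Post-processing

All reported summaries are invariant to cluster relabelling:

* **Similarity matrix** $S_{ij}$: fraction of retained iterations in which
  $i$ and $j$ share a cluster. Internally the thinned allocation matrix is
  stored and $S$ is built by one sparse indicator cross-product, which is
  numerically identical to per-iteration accumulation and far faster in R.
* **Best partition**: the deterministic clustering minimising
  $\sum_{i<j}(S_{ij} - A_{ij})^2$. Candidates come from
  partitioning-around-medoids on $1 - S$ over a range of group counts (PAM's
  BUILD initialisation is deterministic, so the whole procedure is); for
  $n \le 8$ all set partitions are enumerated instead and the global optimum
  is guaranteed — this doubles as the oracle against which the PAM route is
  tested.
* **Group risks**: at each retained iteration the group risk is the average
  of its members' per-subject risks, and the sample-average risk
  $\bar\theta$ is recomputed *per iteration* (the coherent Bayesian reading;
  a fixed posterior mean would understate uncertainty). Exceedance
  probabilities $P(\theta_g > \bar\theta)$ use strict inequalities, ties
  counting to neither side — a measure-zero event for continuous traces that
  only matters in degenerate test fixtures.
* **Posterior odds ratios**
  $\theta_g(1-\theta_{ref})/(\theta_{ref}(1-\theta_g))$ are computed per
  iteration against the lowest-risk group by default and summarised by the
  posterior mean, an equal-tailed 95% credible interval (not HPD — the
  conventional default), and $P(\mathrm{OR} > 1)$.
* **Profile deviations**: per group, covariate and category, the 95%
  interval of the difference between the group's category frequency and the
  whole-sample frequency, computed from the imputation-completed covariates
  at each iteration. Using completed-data empirical frequencies (rather than
  $\phi$ draws) keeps the quantity well defined when a best-partition group
  spans several sampler clusters within an iteration. The flip side: the
  across-iteration variability comes only from the imputed entries, so for a
  fully observed covariate the interval degenerates to a point and even a
  tiny constant difference is classed as excluding zero — read the deviation
  table together with the magnitude of `mean`, not the class alone.
* **Model fit**: the squared-residual sum $\sum_i (y_i - \hat p_i)^2$, a
  logistic-regression-type residual criterion comparable across models on
  the same subjects.

## The MDR comparator

Multifactor dimensionality reduction is included as the model-free
comparator: every cell of a factor combination is labelled high or low risk
by whether its case:control ratio exceeds a threshold (default 1), with
10-fold outcome-stratified cross-validation giving a mean prediction
accuracy and a cross-validation consistency (folds in which the combination
was the training-accuracy winner). Deterministic conventions cover the
sparse-cell cases MDR is known to handle poorly: unseen test cells predict
"low" (the majority class below 50% prevalence), non-empty zero-control
cells are "high", and fold-winner ties break lexicographically by factor
indices. Stratified folds are used because unstratified 10% folds of a
~10%-prevalence sample would frequently contain no cases at all.

## The synthetic generator

`syntheticProfiles()` draws data exactly from the model the sampler assumes:
labels from the mixing weights, covariates from cluster-specific category
probabilities, outcome from cluster risks (optionally with a confounder
offset), missingness applied MCAR per covariate. Shipped scenarios:

* `paper_shape` — 829 subjects, nine covariates (three binary, four 3-level,
  two 4-level), clusters of relative size 96/112/621 with risks
  0.15/0.12/0.09, 34% missingness on the 4-level ordinal exposure and 6% on
  a 3-level one: the shape of a nested case-control air pollution study with
  roughly 10% outcome prevalence.
* `null` — one cluster, risk 0.1: nothing to find.
* `separable` — three equal clusters with risks 0.05/0.10/0.25 and each
  cluster concentrating 70–85% of mass on its own category of every
  covariate; planted high-vs-low odds ratio 6.33.
* `xor_pair` — outcome driven purely by the interaction of two binary
  factors, marginals null.

What the generator does *not* emulate: missingness tied to study centre
(arguably missing-at-random by centre in multicentre data; the generator is
MCAR only), matched-set sampling, continuous covariates, and
covariate-covariate dependence within clusters beyond what the mixture
induces. Passing recovery tests therefore shows the machinery is correct
under its own assumptions, not that those assumptions hold for any given
study.

## Numerical choices and degenerate inputs

* Stick fractions are clamped to $[10^{-12}, 1 - 10^{-12}]$ and plain-mode
  risks to the same band, so logs never overflow; category probabilities are
  floored at $10^{-300}$ inside the allocation log-likelihood (a genuinely
  zero $\phi$ then behaves as $-\infty$ and the cluster is never chosen).
* `probsToThresholds()` rejects zero-probability categories (coincident
  thresholds); `ordinalProbs()` rejects non-increasing thresholds.
* Allocation ties in the Gumbel-max draw resolve to the first index — a
  measure-zero event kept deterministic.
* A proposal scale of zero is a valid degenerate input everywhere and leaves
  the state unchanged.
* Empty clusters draw all parameters from their priors, which is what makes
  the truncated representation of the varying cluster count work.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs are sized for a single CPU: the
end-to-end recovery run uses the `separable` scenario at $n = 900$ with
6000 sweeps (2000 burn-in, thinning 4, truncation 25), which recovers the
planted partition with adjusted Rand index above 0.9 and covers the planted
risks and odds ratio; the conjugate-oracle runs retain 20000 draws; the
imputation comparison pairs complete and 30%-masked runs at $n = 500$. These
are the package's chosen reference sizes; larger analyses simply scale the
iteration counts.

## Known limitations

* Pure-R sampler: a few thousand subjects with the default 30000 sweeps is
  minutes of runtime; far larger problems would want a compiled allocation
  kernel.
* The truncated stick-breaking representation approximates the full
  Dirichlet process; the tail-mass message is the guard.
* Best-partition search over PAM candidates is a heuristic for $n > 8$; it
  matches the exhaustive optimum in testing on clean and noisy block
  structures, but no global guarantee exists.
* Posterior-mean odds ratios are upward-skewed for small groups (the OR is a
  convex functional); the credible interval is the more honest summary.
* Ordinal covariates with very many categories would mix slowly under
  one-threshold-at-a-time moves.
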