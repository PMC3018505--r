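# profilereg

Bayesian profile regression for case-control studies with categorical and
ordinal exposures.

## What problem this solves, and for whom

Epidemiologists studying multifactorial diseases — air pollution and lung
cancer in nonsmokers is the archetype — usually hold a handful of correlated,
individually weak categorical risk factors. Regression with all interactions
is underpowered and collinear; variable selection often returns nothing.
Profile regression changes the unit of inference to the **exposure profile**
x<sub>i</sub> = (x<sub>i1</sub>, …, x<sub>iP</sub>): subjects are clustered
by profile while, in the same model, each cluster is linked to the outcome,
so disease status and covariate patterns inform each other.

The model couples two submodels, fitted jointly by MCMC:

* **Assignment submodel** — a Dirichlet process mixture (truncated
  stick-breaking) over profiles. Cluster k holds category probabilities
  φ<sub>k</sub><sup>p</sup>(x) per covariate: Dirichlet–multinomial for
  nominal covariates; for ordinal covariates an ordered-threshold probit,
  φ<sub>k</sub><sup>p</sup>(j) = Φ(λ<sub>j+1</sub>) − Φ(λ<sub>j</sub>) with
  strictly increasing thresholds, which respects category order and nothing
  else. The number of occupied clusters is random and adapts to the data.
* **Disease submodel** — per-cluster risk θ<sub>k</sub> with
  P(y<sub>i</sub> = 1) = θ<sub>k</sub>, or, adjusting for confounders w,
  logit P(y<sub>i</sub> = 1) = βw<sub>i</sub> + θ<sub>k</sub> where
  θ<sub>k</sub> is the baseline log-odds at the confounder reference.

Missing covariate entries are imputed stochastically inside the Gibbs
sampler as part of the joint posterior. Post-processing is entirely
label-invariant: an n×n **similarity matrix** of posterior co-clustering
frequencies, a deterministic **best partition** matching it in least
squares, per-group posterior risks via per-iteration averaging, exceedance
probabilities P(θ<sub>g</sub> > θ̄) against the per-iteration sample-average
risk, and posterior odds ratios
OR = θ<sub>g</sub>(1 − θ<sub>ref</sub>) / (θ<sub>ref</sub>(1 − θ<sub>g</sub>))
with 95% credible intervals against the lowest-risk group. A multifactor
dimensionality reduction (MDR) comparator and a synthetic-data generator
with planted cluster structure round out the package.

## Worked example

Three planted clusters with risks 0.05/0.10/0.25 and well-separated
profiles, n = 900 (`separable` preset):

```r
library(profilereg)

sim <- syntheticPreset("separable", n = 900, seed = 65)
summarizeProfiles(sim$data)$caseFraction
#> [1] 0.1311111

fit  <- profileRegression(sim$data, nIter = 6000, burnIn = 2000, thin = 4,
                          truncation = 25, seed = 65)
part <- bestPartition(similarityMatrix(fit), gRange = 1:10)
groupSizes(part)
#> 305 304 284 1 1 1 1 1 1 1

tab <- groupSummary(fit, part)
tab[1:3, c("group","size","risk","pAbove","or","orLower","orUpper","pOrGreater1")]
#>   group size   risk pAbove   or orLower orUpper pOrGreater1
#> 1     1  305 0.0907      0 1.36   0.692    2.30       0.815
#> 2     2  304 0.0713      0 1.00   1.000    1.00          NA
#> 3     3  284 0.2547      1 4.68   2.832    7.82       1.000
```

Reading this: three large groups recover the planted clusters (adjusted Rand
index 0.95 against the planted labels; the singletons are subjects the
sampler genuinely cannot place, split off by the least-squares criterion).
Group 3 is flagged high-risk — its posterior mean risk 0.25 matches the
planted 0.25, P(θ<sub>3</sub> > θ̄) = 1, and its posterior odds ratio
against the lowest-risk group is 4.7 (95% CI 2.8–7.8), the interval covering
the planted OR of 6.3. Group 2 is the reference (lowest risk), so its OR is
exactly 1. `profileDeviations(fit, part)` then shows *which* covariate
categories make each group distinctive, as 95% intervals of the difference
from the population frequency.

`mdrScan()`, `mdrCrossValidate()` and `mdrLabelCells()` provide the MDR
comparator; `readProfileDataset()`/`writeProfileDataset()` handle delimited
text with a YAML/JSON covariate declaration; `inst/scripts/profilereg` is a
command-line front end (`fit`, `summarize`, `mdr`, `simulate`).

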