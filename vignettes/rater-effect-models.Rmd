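---
title: "Rater-effect IRT models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rater-effect IRT models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raterirt)
```

## The measurement problem

In performance assessment — essay scoring, report grading, peer
assessment — an examinee's outcome on a task is scored by human raters on
an ordinal scale $1, \dots, K$. The observed rating $x_{ijr}$ (task $i$,
examinee $j$, rater $r$; $-1$ for missing) confounds three things: the
examinee's latent ability $\theta_j$, properties of the task, and
idiosyncrasies of the rater. Raters differ systematically in *severity*
(overall harshness), *consistency* (how reliably their ratings track
outcome quality) and *range restriction* (overuse of a few categories).
Ability estimates that ignore these effects inherit the raters' biases.

`raterirt` implements five polytomous item-response models that
parameterize rater effects to different depths, together with the
machinery to estimate them, compare them, and study them by simulation.

## The five models

All models assume local independence: the likelihood is the product of
the category probabilities over non-missing ratings.

**MFRM** (many-facet Rasch model) — a partial credit model with an
additive rater severity:
$$P_{ijrk} \propto \exp \sum_{m=1}^{k} (\theta_j - \beta_i - \beta_r - d_m),$$
with $\beta_{r=1} = 0$, $d_1 = 0$, $\sum_{k \ge 2} d_k = 0$ for
identifiability. Severity only.

**Patz1999** — a generalized partial credit model whose rater severity
$\rho_{ir}$ is task-specific:
$$P_{ijrk} \propto \exp \sum_{m=1}^{k} \alpha_i(\theta_j - \beta_{im} - \rho_{ir}),$$
with $\beta_{i1} = 0$ and the first rater's severity fixed at 0 within
each task. Captures rater-by-task interaction and task discrimination.

**Ueno2008** — a graded response model with *per-rater* ordered category
thresholds $\epsilon_{rk}$ (boundary curves
$[1+\exp(-\alpha_i(\theta_j - b_i - \epsilon_{rk}))]^{-1}$,
$\epsilon_{11} = -1$ fixed). The spacing of a rater's thresholds
expresses range restriction; a uniform shift of them is severity.

**Uto2016** — a graded response model with rater severity $\epsilon_r$
and rater consistency $\alpha_r$ (boundary curves
$[1+\exp(-\alpha_i \alpha_r(\theta_j - b_{ik} - \epsilon_r))]^{-1}$,
$\alpha_{r=1} = 1$, $\epsilon_1 = 0$). Leanest parameterization with a
consistency parameter when raters are numerous.

**HRM** (hierarchical rater model) — two stages: a PCM generates a latent
*ideal rating* $\xi_{ij}$ per outcome, then a Gaussian signal-detection
kernel generates observed ratings,
$p(x = k \mid \xi) \propto \exp\{-[k - (\xi + \sigma_r)]^2 / 2\psi_r^2\}$.
$\sigma_r$ is rater severity (note it *raises* ratings as it grows — it
shifts the kernel's center), $1/\psi_r^2$ rater consistency. Two
likelihood conventions coexist for the HRM and the package implements
both: `log_likelihood()` defaults to the observed-data likelihood that
marginalizes $\xi$ per observation (the generative definition, used for
ability estimation), while the information criteria condition on the
sampled $\xi$ — consistent with the parameter-count accounting, which
counts the $I \times J$ ideal ratings as parameters. Conditioning also gives WAIC its characteristic heavy
penalty for the HRM: the pointwise log-probabilities jump whenever a
latent ideal rating flips between draws, so the posterior-variance
penalty grows with the instability of $\xi$.

A boundary-curve note: graded-response boundary definitions are
implemented for $k = 1..K-1$ with $P^*_0 = 1$, $P^*_K = 0$ — the only
reading under which category probabilities sum to one. Boundary
differences are computed in log space
($\log(\sigma(a) - \sigma(b)) = b + \log(e^{a-b}-1) - \log(1+e^a) -
\log(1+e^b)$), so likelihoods stay finite for extreme draws; adjacent-
category models use max-subtracted softmax.

## Estimation

Each model is estimated by a single-chain Metropolis-within-Gibbs
sampler (compiled code): Gaussian random-walk proposals per scalar
parameter, log-scale proposals for positivity-constrained
discriminations and spreads, order-violating threshold proposals
rejected, sum-to-zero blocks parameterized by their $K-2$ free elements
with the last set deterministically, and exact categorical Gibbs draws
for the HRM's ideal ratings. Proposal scales adapt toward a 40%
acceptance rate during burn-in only and are frozen afterwards, so the
retained draws form a valid Markov chain. Acceptance rates are reported
per block (typical values 0.3–0.5); no convergence diagnostic gates the
pipeline, but the log-likelihood trace is available via `autoplot()`.

Priors default to the same distributions used to generate synthetic
truth (see below) with $\theta_j \sim N(0,1)$ — expected-a-posteriori
(EAP) estimation needs proper priors, and using the generating
distributions is the one internally consistent default. Ordered blocks
get the multivariate normal prior truncated to the ordered region.

The default schedule — 20,000 iterations, burn-in 10,000, thinning 100 —
retains 100 draws (at iterations 10,100, 10,200, …, 20,000). EAP
estimates are per-parameter means of retained draws; the HRM's ideal
ratings, being category-valued, use the posterior modal category
instead.

`estimate_ability_given_params()` re-scores examinees with all rater and
task parameters held fixed. The examinees are then conditionally
independent with one-dimensional posteriors, so the package integrates
each exactly on a 241-point grid over $[-6, 6]$ rather than running a
chain: the same EAP estimand, with no Monte-Carlo noise. No scale
linking is needed between complete-data and reduced-data abilities
because the parameters are shared.

## Model comparison

Four criteria are computed on a common "larger is better" log scale:
`aic = logL(EAP) - p`, `bic = logL(EAP) - (p/2) ln n` (with `n` the
count of non-missing ratings), `waic = lppd - p_waic` (variance-form
penalty), and the log marginal likelihood estimated by the harmonic mean
of the likelihood over posterior draws (noisy, as is well known; the
estimator is pluggable). Parameter counts `p` follow the models'
conventional formulas verbatim — including the HRM's latent ideal ratings, and an
MFRM count that exceeds its free-parameter count by one; both
conventions are kept so that criterion values remain comparable across
implementations. Rank 1 goes to the maximal score, ties receive
averaged ranks.

## The synthetic-data generator

`draw_true_params()` draws truth from: $\log \alpha_i \sim N(0.1, 0.4)$,
$\log \alpha_r, \log \psi_r \sim N(0, 0.5)$ (second arguments are
variances — consistent with the ordered-block covariance, whose diagonal
0.25 is unambiguously a variance), all location parameters and abilities
$N(0,1)$, and ordered threshold vectors from a multivariate normal with
mean $(-1.5, -0.75, 0.75, 1.5)$ and covariance 0.25/0.16, sorted
ascending (for $K \ne 5$ the means are evenly spaced on $[-1.5, 1.5]$ —
the reference values exist only for $K = 5$). Identifiability fixes are
applied after drawing; the first rater's first threshold is set to
$-1.0$ with any later threshold pushed up to preserve strict order.

`apply_transform()` injects six bias patterns (rules A–F): randomized
ratings for 60% of raters (A) or tasks (B), two-category collapse around
the unit mean (C, D), a constant per-cell severity shift clipped to the
scale (E), and all of them composed in the order A→E with independent
selections (F). Counts use `round(0.6 · units)` and
`round(0.7 · entries)`; rule C/D unit means are taken before
transformation (defining it after transformation would be circular).
`judge_pair()` keeps exactly two raters per outcome, balanced within
task — the assignment scheme is this package's construction; only the
two-raters-per-outcome property is prescribed.

What the generator emulates is the *structure* of real rating data —
design dimensions, category counts, rater heterogeneity on the stated
scales, stylized biases. What it does not emulate: rater drift over
time, outcome-order effects, non-logistic response processes, or
correlated rater panels. Passing recovery tests therefore demonstrates
internal consistency of estimation, not validity on any particular
empirical data set.

## Replication sizes and numerical choices

The package's replication runs use desk-scale sizes chosen to keep a
complete run on one CPU comfortable while staying faithful to the study
protocol: parameter recovery at $J=100, R=10, I=5, K=5$ uses 5
repetitions of 6,000-iteration chains (burn-in 3,000, thin 30 — the same
100 retained draws as the full schedule; recovery error is dominated by
posterior spread, not chain length); the bias-injection
comparisons at $J=100, R=5, I=5, K=5$ use 3 repetitions with
3,000-iteration chains (burn-in 1,500, thin 15, 100 retained draws).
Stochastic checks are asserted within Monte-Carlo tolerances rather than
to the third decimal.

Other numerical choices: quadrature grid $[-6, 6]$ × 241 points (ability
posteriors are effectively supported well inside this range under the
$N(0,1)$ prior); probability floors are never applied — stability comes
from log-space computation; ties in the ranking use R's average-rank
convention; the population (divide-by-$n$) convention is used for the SD
of absolute errors; ordered truth draws are sorted rather than
rejection-sampled (the two are equivalent up to relabeling of an
exchangeable draw).

## Known limitations

* The harmonic-mean evidence estimator has heavy-tailed error; treat
  `log_ml` rankings with more caution than WAIC/BIC.
* MFRM's overall location is identified only softly through the ability
  prior; a common offset of order $1/\sqrt{J + I}$ between estimated and
  true task difficulties is an irreducible part of its recovery error.
* The HRM mixes slowly and recovers poorly relative to the other models
  at these design sizes — a property of the model's parameter count, not
  a sampler defect; its recovery error is reported, not hidden.
* Single chain by design; users wanting R-hat diagnostics can run
  several fits with different seeds and compare draws.

## A worked example

```{r example, eval = FALSE}
library(raterirt)

truth <- draw_true_params("uto2016", J = 30, I = 5, R = 5, K = 5, seed = 1)
data  <- simulate_ratings(truth, seed = 2)

fit <- fit_rater_model(data, "uto2016",
                       mcmc_config(3000, 1500, 15, seed = 3))
eap(fit)                  # parameter bundle at posterior means
tidy(fit)                 # tibble of estimates and posterior SDs
ab <- estimate_ability_given_params(judge_pair(data, seed = 4), eap(fit))

fits <- lapply(c("mfrm", "uto2016"), \(m)
  fit_rater_model(data, m, mcmc_config(3000, 1500, 15, seed = 3)))
criterion_scores(fits, data)
```
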