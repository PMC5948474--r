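# raterirt

Item response theory (IRT) models for **rater-mediated performance
assessment**: essays, reports, and peer assessments in which raters award an
ordinal category 1..K to each examinee's work on each task. Ratings confound
examinee ability with rater severity, consistency and range restriction;
`raterirt` implements five polytomous IRT models that parameterize these
rater effects to different depths, estimates them by MCMC, and compares them
with information criteria. It is aimed at psychometricians and applied
researchers who need bias-adjusted ability estimates from multi-rater rating
designs, and at methodologists studying when each rater model pays off.

## Models

With ability θ_j, task parameters and rater parameters, the probability that
rater r gives category k to examinee j's outcome on task i is:

| id | model | rater effects |
|----|-------|----------------|
| `mfrm` | many-facet Rasch model: PCM with additive rater severity β_r | severity |
| `patz1999` | GPCM with per-task rater severity ρ_ir | severity × task |
| `ueno2008` | GRM with per-rater ordered thresholds ε_rk | severity, range restriction |
| `uto2016` | GRM with rater consistency α_r and severity ε_r | severity, consistency |
| `hrm` | hierarchical rater model: PCM → latent ideal rating ξ_ij → Gaussian signal-detection stage (σ_r, ψ_r) | severity, consistency |

For example the MFRM is
P(x_ijr = k) ∝ exp Σ_{m≤k} (θ_j − β_i − β_r − d_m), and the
`uto2016` boundary curves are [1 + exp(−α_i α_r (θ_j − b_ik − ε_r))]^{−1}.
All identifiability constraints (fixed first-rater parameters, ordered
thresholds, sum-to-zero category blocks) are enforced in the constructors,
the sampler, and the synthetic-truth generator.

Estimation is single-chain Metropolis-within-Gibbs (compiled core) with EAP
point estimates from thinned post-burn-in draws; model comparison uses AIC,
WAIC, BIC and the log marginal likelihood on a common larger-is-better log
scale. See the vignette `vignettes/rater-effect-models.Rmd` for the full
method description and design notes.

## A worked example

```r
library(raterirt)

# simulate a 30-examinee, 5-task, 5-rater, 5-category study from the
# rater-consistency GRM, then fit it back
truth <- draw_true_params("uto2016", J = 30, I = 5, R = 5, K = 5, seed = 1)
data  <- simulate_ratings(truth, seed = 2)
data
#> <rating_data> 750 ratings: J=30 examinees, I=5 tasks, R=5 raters, K=5 categories

fit <- fit_rater_model(data, "uto2016", mcmc_config(3000, 1500, 15, seed = 3))
est <- eap(fit)
round(est$alpha_rater, 2)   # estimated rater consistencies (first fixed at 1)
round(truth$alpha_rater, 2) # truth
rmse(est$theta, truth$theta)

# compare candidate models on the same data
fits <- lapply(c("mfrm", "uto2016"), \(m)
  fit_rater_model(data, m, mcmc_config(3000, 1500, 15, seed = 3)))
criterion_scores(fits, data)[, c("model", "aic", "waic", "bic", "log_ml")]
```

Example output (seeds as above):

```
#> [1] 1.00 0.96 1.14 0.91 0.40
#> [1] 1.00 0.93 1.32 0.96 0.38
#> [1] 0.2536
#>     model       aic      waic      bic    log_ml
#> 1    mfrm -1070.815 -1071.967 -1170.15 -1053.966
#> 2 uto2016  -916.679  -907.458 -1062.21  -887.231
```

The fit recovers the simulated rater consistencies (rater 5 is noisy at
α ≈ 0.4, rater 3 sharp at α ≈ 1.3), the ability RMSE is about 0.25 logits,
and all four criteria prefer the generating model over the MFRM by a wide
margin.

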