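# tigermove

Movement-ecology analysis of hourly GPS telemetry from dispersing large
carnivores crossing human-dominated landscapes. The package takes raw,
gappy fix series plus a raster covariate stack (NDVI, built-up fraction,
water, forest classes) and answers three questions a dispersal study asks:

1. **How does the animal move?** Step lengths and turning angles by day
   and night, with rank-sum comparisons, after continuous-time
   correlated-random-walk (CTCRW) imputation of missing fixes.
2. **When is it travelling versus encamping?** A two-state hidden Markov
   model segments the trajectory into behavioural states and links the
   switching rates to environmental covariates.
3. **What habitat does it select while moving?** An integrated
   step-selection function (iSSF) with matched random steps, conditional
   logistic regression and relative selection strength.

It is aimed at movement ecologists who want the full
prepare → impute → segment → select pipeline as plain, testable R, with a
synthetic-data generator so every stage can be validated without any field
data.

## Models

**Gap imputation.** The CTCRW treats velocity as an Ornstein–Uhlenbeck
process, `dv = −β v dt + σ dW`, and position as its integral, observed
with Gaussian GPS error. The model is discretized exactly over each
inter-fix interval and fitted by Kalman-filter maximum likelihood; missing
hourly slots get the Kalman-smoother mean position.

**Behavioural segmentation.** Steps `s_t` follow a zero-inflated gamma per
state (point mass π₀ at exactly 0 m), turns `θ_t` a wrapped Cauchy with
mean ϑ and concentration ρ. The 2×2 transition matrix Γ(z) has logistic
off-diagonals,

    γ_kj(z) = logit⁻¹(α_kj + β_kjᵀ z),

with standardized distance-to-village, distance-to-water and NDVI as
covariates z. The pooled forward likelihood (bursts restart at the local
stationary distribution δ(z), `δ₁ = γ₂₁/(γ₁₂+γ₂₁)`) is maximized on the
working scale; Viterbi decoding yields the most probable state sequence,
activity budgets and stationary-state curves with delta-method CIs.

**Habitat selection.** For every used step, 15 random steps are drawn from
a tentative gamma/von-Mises kernel and projected from the previous
bearing. Conditional logistic regression (Newton–Raphson on the exact
conditional likelihood) contrasts the used against the available
endpoints, with movement-adjustment terms (step, log step, cos turn,
optionally diel-specific) correcting the tentative kernel. Relative
selection strength between habitat compositions x₁, x₂ is
`RSS = exp(β̂ᵀ(x₁ − x₂))` with a Wald interval.

Rasters are plain-text ESRI ASCII grids; tracks are CSV; everything is
seeded and reruns byte-identically.

## Worked example

Simulate a landscape and two state-switching tracks, then run the
segmentation stage:

```r
library(tigermove)

sc    <- sim_config(seed = 11, nrow = 80, ncol = 80,
                    track_length = 1000, n_animals = 2)
stack <- make_landscape(sc)
sims  <- lapply(1:2, function(i)
  simulate_hmm_track(sc, stack, id = paste0("tiger", i), seed = 1100 + i))
steps <- do.call(rbind, lapply(sims, function(s) compute_steps(s$track)))
steps <- attach_covariates(assign_diel(steps), stack, wrap = TRUE)

fit <- fit_hmm(steps, covariates = c("dist_village", "ndvi"), n_starts = 1)
fit
#> 2-state movement HMM (2000 steps), logLik = -15768.23
#>  encamping  mu = 98.6 m, sigma = 48.4 m, zeromass = 0.006, angle mean = 3.01, conc = 0.32
#>  travelling mu = 691.2 m, sigma = 1009.2 m, zeromass = 0.049, angle mean = -0.03, conc = 0.71
#>  transition covariates: dist_village, ndvi

round(state_budget(viterbi(steps, fit)), 3)
#>  encamping travelling
#>       0.38       0.62

displacement_summary(steps, by = "diel")
#>    diel    n     mean       se
#> 1   day 1004 441.3771 25.78648
#> 2 night  996 446.4314 25.90503
```

The generator's states used short steps of mean 100 m with turn-backs and
long directed steps of mean 700 m; the fit recovers 98.6 m and 691.2 m,
an angle mean near π for encamping (turn-backs) and near 0 for travelling,
and decodes a 38/62 activity budget for this landscape. `stationary_curve()`
then traces how the encamping probability responds to each covariate, and
`build_strata()` + `compare_models()` + `rss()` run the habitat-selection
stage (see the methods vignette).

The whole pipeline — regularization, CTCRW imputation, displacement
tables, HMM, decoding, iSSF, RSS, manifest — runs from one configuration:

```r
report <- run_pipeline(list(seed = 2, outdir = "out"))
```

or from the shell via `inst/scripts/tigermove.R` (`simulate`, `validate`,
`run-all`).

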