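---
title: "Models and methods in tigermove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tigermove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tigermove)
```

tigermove analyses hourly telemetry of dispersing large carnivores in
three linked stages: trajectory preparation with gap imputation,
behavioural segmentation with a hidden Markov model (HMM), and habitat
selection with an integrated step-selection function (iSSF). This
vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the places where the design was genuinely open
and a decision had to be made. It states no empirical result beyond what
the package's tests and acceptance script themselves compute.

## Trajectory preparation

**Regularization.** Fixes are snapped to an hourly lattice anchored at
the first fix's nearest whole hour. A fix more than 5 minutes
(`tolerance = 300` s) from its nearest slot is dropped and counted;
duplicate slots keep the earliest fix with a warning. Runs of empty slots
up to `max_gap` (default 24 h) become explicit missing slots to be
imputed; longer gaps split the track into independent bursts. The 24-h
default reflects a judgement call: predicting a full day of carnivore
movement from a velocity-autocorrelation model is not defensible, so
longer gaps are treated as breaks rather than bridged.

**CTCRW imputation.** The continuous-time correlated random walk models
each coordinate's velocity as an Ornstein–Uhlenbeck process
($dv = -\beta v\,dt + \sigma\,dW$, $\beta$ in 1/h, $\sigma$ in
m·h^-3/2) and position as its integral, observed with Gaussian error
`obs_sd` (m, default fixed at 0 for error-free synthetic data, estimable
for field data). The transition and innovation matrices are the exact
discretization over each interval, the likelihood is the Kalman-filter
prediction-error decomposition, and missing slots receive
Rauch–Tung–Striebel smoother means. The position prior at each burst
start is diffuse with fixed variance 1e7 m² centred on the first observed
fix; fixing the constant makes the likelihood a well-defined function of
the parameters and lets tests compare the filter against the closed-form
joint Gaussian density of the same model. Fitting is quasi-Newton on
(log β, log σ[, log obs_sd]).

**Steps and diel labels.** Step length is the Euclidean distance between
consecutive fixes; the turning angle is the signed
(counterclockwise-positive) change of bearing wrapped to (-π, π], left
missing at burst starts and around zero-length steps rather than coded as
zero. Day is the half-open local-clock window [06:00, 18:00) by default —
the analysis needs only a reproducible dichotomy, and a sunrise/sunset
ephemeris is deliberately out of scope. On the hourly lattice, step
length in meters and displacement in m/h coincide.

**Displacement inference.** Group summaries report mean ± SE (SE missing,
not zero, for single-step groups). The day/night comparison is a
Mann–Whitney U with midranks, tie-corrected normal approximation and
continuity correction; for min(n) ≤ 8 an exact two-sided p-value is
computed by full enumeration of group labelings, which handles ties
without approximation.

## Behavioural segmentation

Each state k ∈ {encamping, travelling} emits step lengths from a
zero-inflated gamma — point mass π₀ₖ at exactly 0 m (two fixes coinciding
to the millimeter; no jitter threshold is applied), gamma with mean μₖ
and sd σₖ otherwise — and turning angles from a wrapped Cauchy with mean
ϑₖ and concentration ρₖ ∈ [0, 1). Default starting values are the
field-standard short/long-step pair: 100/50 m with π₀ = 0.01 and ρ = 0.3
for encamping, 700/1000 m with π₀ = 0.05 and ρ = 0.7 for travelling. The
angle means are estimated, initialized at 0: a concentration "toward
turning back" conventionally implies ϑ ≈ π, but hard-coding π would bake
an assumption into the likelihood that the data can decide.

Transition probabilities follow logistic regressions on standardized
covariates (distance-to-village, distance-to-water, NDVI by default),
evaluated at each step's start location — the endpoint of the previous
step (one-lag convention). Bursts enter a pooled likelihood and restart
at the stationary distribution of the local transition matrix; this
avoids free initial-distribution parameters that a handful of burst
starts cannot inform. Zero-mass parameters are included only when the
data contain exact zeros; otherwise their likelihood contribution is
unidentifiable and the logit parameter would run to -∞.

Numerics: the forward recursion and Viterbi are compiled (scaled forward
in probability space with per-step renormalization; max-product with
backtracking, ties toward the lower state index); optimization is BFGS on
the working scale (log μ, log σ, logit π₀, logit ρ, unconstrained ϑ and
transition coefficients), by default multi-started from the standard
initial values plus four jittered starts (sd 0.3 on the working scale,
seed-controlled). Confidence intervals come from the inverse observed
information on the working scale, back-transformed; states are relabelled
after fitting so state 1 has the smaller step mean. The engine is written
for K states; the fitting surface supports and exercises K = 2, the
established choice for dispersal (encamping/travelling) data.

Stationary-state curves sweep one covariate over its observed range with
the others held at their standardized mean, using
δ₁(z) = γ₂₁(z)/(γ₁₂(z)+γ₂₁(z)); intervals are delta-method on logit δ₁,
which keeps them inside (0, 1).

## Habitat selection

A tentative movement kernel is fitted to the used steps: gamma by maximum
likelihood via the exact profile-likelihood root (for fixed shape the
rate is closed-form; the profile score has a unique root bracketed and
solved to 1e-12 — more robust at hundreds-of-meters scales than
general-purpose optimization, and cross-checked against an independent
gamma fitter in the tests), von Mises by the resultant-length equation
A₁(κ) = R̄ solved on the scaled Bessel ratio.

Each used step with a defined previous bearing becomes a stratum: 15
random steps (lengths from the gamma, turns from the von Mises, applied
to the previous bearing) are generated under a per-stratum substream of
the master seed, so stratum sets are reproducible regardless of
processing order. Covariates are sampled at all endpoints (bilinear for
continuous layers, nearest for classes); candidates falling off the stack
are dropped with counts reported, the used step never is, and a stratum
survives while at least two candidates remain. Continuous covariates are
standardized over all rows of the strata (used + available) by default,
with the constants stored for back-transformation; a fixed constants
table can be supplied instead when an external scale is required.

Three candidate models are predefined: habitat only; habitat plus shared
movement adjustments (step, log step, cos turn); and the diel-structured
model with day/night-specific forest classes and movement adjustments
plus a night turn term. The third reconstructs the structure of the full
selection model from its published coefficient table (the original
specification table is unavailable); all three are plain term lists a
user can override. "Turning angle" enters as cos θ, the standard
movement-kernel correction, since the source table does not state a
transform. The forest reference class is non-forest, and water cells map
to non-forest in the 3-class scheme — the merge rules name only the
forest and open-forest constituents, and this keeps the classification
total. Conditional logistic estimation is Newton–Raphson with step
halving on the exact conditional likelihood; divergence past |β| = 30 on
the standardized scale or a singular information matrix is reported as
probable complete separation rather than returned as a fit. AIC ranks the
candidates; RSS contrasts exclude movement-adjustment terms and refuse
terms absent from the fit.

## Landscape preparation

Settlements are cells whose built-up fraction is ≥ 0.75. Distances are
exact Euclidean cell-center-to-cell-center transforms (separable
lower-envelope algorithm, verified against brute force); sub-cell
"edge of settlement" geometry is unrecoverable from a 100 m raster, so
the cell-center convention is documented and tests are exact under it.
Layers align on a shared 100 m grid (bilinear for continuous, nearest for
categorical — preventing phantom classes). All coordinates are planar
meters; no CRS mathematics is performed. Rasters read and write the
plain-text ESRI ASCII grid format, with layer roles declared in a YAML
map.

## The synthetic generator

`make_landscape()` emulates the covariate structure the analysis assumes:
NDVI as a torus-smoothed Gaussian random field rescaled to [-0.1, 0.6],
settlements as dilated random patches in a built-up fraction layer, water
as a meandering rasterized polyline, and six NDVI-thresholded forest
classes with water and settlement overrides. Defaults (100×100 cells at
100 m, 3 villages) give landscapes with all three merged forest classes
and non-degenerate distance gradients.

`simulate_hmm_track()` is the generative mirror of the segmentation
model: transitions from Γ(z) at the walker's location (covariates
standardized by landscape-wide constants), emissions from the
zero-inflated gamma and wrapped Cauchy, with truth defaulting to the
standard initial values above (switching intercepts 0.15 and 0.07, giving
a long-run budget near 32/68; distance-to-village and NDVI push toward
travelling, water has no effect; angle means π and 0). Boundary handling
was a genuinely open choice: reflecting a step at the landscape edge
shortens the chord between recorded hourly fixes, so recorded steps near
walls no longer follow the generating gamma and recovery checks would be
biased by the geometry rather than the estimator. The default is
therefore `boundary = "wrap"` — covariates are looked up on the periodic
tiling of the landscape while positions run unbounded, keeping the
generative HMM exact everywhere; `"reflect"` is available (and counted)
for strictly bounded uses.

`simulate_ssf_track()` draws each step exactly from the continuous
selection density kernel × exp(βᵀz), truncated to the landscape, by
rejection sampling with a cellwise bound on the habitat weight. An
earlier candidate-set design (choose one of C kernel draws with
probability ∝ exp(βᵀz)) was replaced: the finite choice set attenuates
the realized selection by O(1/C), so the generator was not simulating the
model it claims; rejection sampling removes the approximation entirely.
Out-of-extent kernel draws are rejected, matching the estimator's
truncation of availability to the stack.

`inject_missingness()` drops interior fixes independently at the given
rate (endpoints retained), producing the irregular series the
regularizer and imputer expect. All generators run from a master seed
through R's Mersenne–Twister; identical seeds give bit-identical output,
which the pipeline's manifest records.

What the generator does *not* emulate: territoriality, home-range
attraction, prey dynamics, GPS fix-success bias correlated with habitat,
and geographic realism. Passing recovery tests therefore demonstrates
estimator correctness under the stated model, not robustness to every
field-data pathology.

## Problem sizes and test design

The test suite checks every recursion against an independent oracle at
enumerable sizes (forward likelihood vs all 2^T sequences for T ≤ 8;
Viterbi vs exhaustive argmax for T ≤ 12; Kalman likelihood vs the joint
Gaussian for ≤ 12 fixes; exact rank-sum p vs full enumeration for
n ≤ 8; Newton–Raphson vs a dense likelihood grid; the distance transform
vs brute force on grids ≤ 50×50). Recovery properties use 50 replicates
of 5×2000-step state-switching tracks (pooled-CI coverage of the
emission means) and 50 replicates of 2000-stratum selection tracks
(per-coefficient Wald coverage) — sizes chosen so each replicate fits a
model in a few seconds while leaving coverage estimates with binomial
error of a few percent. The acceptance script runs one full pass of each
stage at the same sizes.

## Known limitations

- The CTCRW assumes a single movement regime; imputing through a
  behavioural switch smooths it over. Imputation error is reported so
  users can judge the scale.
- GPS error `obs_sd` is weakly identified from hourly fixes alone and is
  best fixed from receiver specifications when known.
- The HMM treats animals as exchangeable (pooled likelihood with
  per-animal bursts); per-animal fits are available but there are no
  random effects.
- Wald inference for the iSSF assumes independent strata; consecutive
  steps share landscape structure, so intervals can be mildly optimistic
  on strongly autocorrelated covariates.
- The 3-class forest merge discards the water class; analyses needing
  water as a habitat class should use the distance-to-water covariate.
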