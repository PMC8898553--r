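---
title: "Models and methods in fishmot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fishmot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fishmot implements the analysis chain for multiple object tracking (MOT)
experiments that contrast naturalistic fish-like motion with classic
ballistic motion: a motion-decomposition layer, two stimulus simulators, an
experiment-design enumerator, a generative signal-detection observer, and
hierarchical Bayesian inference for sensitivity and bias. This vignette
explains each model, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data checks do and do not
establish.

## Trajectory segmentation and the motion model

Fish in an aquarium alternate *waiting* — staying near one spot with small
positional jitter — with sudden *dashes* to a new location.
`segment_trajectory()` formalizes this with a greedy anchored scan: a
candidate waiting phase opens at the current sample, whose position becomes
the anchor; it extends while every sample stays within `radius_px` of the
anchor, and is committed iff it spans at least `min_wait_s` seconds (and
more than one sample, so zero-length phases cannot arise). Everything
between committed waits is a single move phase whose distance is the path
length, mean velocity distance/duration, and direction the angle of the
net displacement. Phases share boundary samples, so their durations tile
the trajectory span exactly.

Parameter choices:

* `radius_px = 60` — the radius used to decompose the original aquarium
  recordings.
* `min_wait_s = 0.2 s` — at 25–30 Hz sampling, anything shorter is one or
  two frames and indistinguishable from sampling noise. Waits shorter than
  this merge into the surrounding move.
* Frame rate of simulated trajectories: 30 Hz (`dt = 1/30`), a typical
  video rate.

The greedy scan is deliberately simple and deterministic so that an
exhaustive oracle — enumerate, for every start sample, the maximal
within-radius run via the full distance matrix, then walk left to right —
must reproduce its waiting set exactly; the test suite checks this
equivalence on randomized wait/dash paths.

Two artifacts of radius-based segmentation are worth knowing. First, the
anchored run keeps early dash samples that are still within the radius, so
measured waits are longer by up to `radius_px / velocity` at each end and
measured dash distances correspondingly shorter by up to one radius per
end. Second, a dash slower than roughly `radius_px / min_wait_s`
(300 px/s at the defaults) spends long enough inside the radius to be
committed as a wait, so slow dashes fragment. Both effects shrink toward
zero as dashes become fast and long relative to the radius; the round-trip
recovery test therefore uses dash distances with mean 8000 px and
velocities with mean 5000 px/s, where the artifacts are well below the
sampling error of the gamma estimates. Inside the 800 px arena with the
default motion model they are material, which is why
`wait_time_fraction()` defaults to the generator's own phase schedule
(ground truth) rather than re-segmentation.

`fit_gamma_mle()` fits the two-parameter gamma law (location fixed at 0)
by maximum likelihood: the shape solves
`log(k) − digamma(k) = log(mean(x)) − mean(log(x))` by safeguarded Newton
iteration with a bisection bracket and the closed-form start
`k₀ = (3 − s + sqrt((s − 3)² + 24 s)) / (12 s)`; the scale is `mean(x)/k`.
Samples must be positive with `n ≥ 3`; equal samples give a
degenerate-sample error (the shape equation has no finite solution). Tests
verify that the optimum dominates a 200 × 200 grid around the
method-of-moments estimate, satisfies the score equations to 1e-6, matches
`MASS::fitdistr`, and recovers known parameters within 3 standard errors
at n = 10⁵.

`default_motion_model()` encodes the generative defaults: waiting
durations Gamma(2, 0.2) s (mean 0.4 s), dash distances Gamma(3, 200) px
(mean 600 px), dash velocities Gamma(12, 30) px/s (mean 360 px/s), jitter
radius 10 px. These were chosen once so that the expected waiting-time
fraction, mean wait / (mean wait + mean dash duration) ≈ 0.18, matches the
roughly 19% waiting / 81% moving split observed in the recordings, while
keeping dashes fast enough to look like dashes at 30 Hz. Dash directions
are recorded during segmentation but generated uniformly on [0, 2π): the
goal of the generator is fish-*like* motion statistics, not a veridical
fish model, and no directional law is part of the model.

## Stimulus simulators

Both simulators live in a circular arena (`arena_spec()`, default 800 px
diameter centered in a 960 × 600 px scene, the size matched to the area of
fish motion in the recordings) and integrate exact straight-line
kinematics sampled at `dt` — there is no ODE error anywhere.

**Ballistic (traditional MOT).** Objects move at a constant `speed`
(default 200 px/s). Bounces are resolved at sampling boundaries, before
each step: if the straight continuation would cross the effective border
(arena radius minus object radius), the velocity is mirrored about the
circle normal at the crossing point, repeatedly if necessary; if two
objects would come within two radii, the velocity components along their
line of centers are exchanged (equal-mass elastic collision) and each
velocity is rescaled to `speed`. The rescaling is the package's resolution
of a genuine conflict: a normal-component exchange preserves individual
speeds only for symmetric impacts, while the stimulus definition requires
exactly constant speed at all times. Exchanging and then pinning the speed
keeps the physical exchange direction and the kinematic invariant; for
head-on symmetric impacts it reduces to the exact mirror swap. Because all
velocity changes happen before the step, every sampled displacement equals
`speed · dt` to machine precision, samples never leave the arena, and
objects never interpenetrate at sample times — the three invariants the
replay checker in the test suite verifies from the sampled tables alone.
Initial positions are uniform in the disc with rejection for overlap, and
a packing error is raised when objects would cover more than 60% of the
arena.

**Fish-like (fake-fish MOT).** Each object alternates waits (duration from
the waiting gamma; position jitters around the anchor by Gaussian steps of
SD `jitter_radius/3`, clipped to `jitter_radius` and to the arena) and
straight dashes (distance and velocity from their gammas, duration =
distance/velocity). The dash direction is uniform, resampled up to 100
times until the endpoint lies inside the arena; if no direction fits (the
drawn distance exceeds the arena everywhere), the distance is truncated at
the border along the last direction. This keeps distances near the gamma
law while guaranteeing containment. There is no object–object collision
handling — real fish pass each other. The generating phase schedule is
attached to every trajectory as ground truth, which is what makes clean
round-trip tests possible. Whether real fish jitter while waiting is not
part of the recorded motion statistics, so `jitter_radius` is a free
parameter; 10 px keeps waits visually alive yet well inside the 60 px
segmentation radius.

All randomness in both simulators flows from the config seed, and
identical configs give bit-identical trajectory tables.

## Experiment designs

`build_design_exp1()` enumerates 23 scenes × set sizes {1, 3, 5} ×
{target, distractor} query = 138 trials with target-query probability
exactly 50%. `build_design_exp2()` gives 23 × {2, 4} × 2 = 92 trials per
condition; the fish condition reuses the same scene at both loads while
each circle condition gets trajectory identifiers of its own.
`counterbalance_orders()` assigns all 3! = 6 block orderings round-robin,
so counts differ by at most one. Where the design procedure is
underdetermined, the enumerator draws uniformly: target sets are sampled
without replacement per trial and independently for the two trials of a
(scene, set size) pair, and the queried distractor is uniform among
non-targets. Timing constants (75 ms fixation, 3 s cue, 10 s motion) are
metadata in `design_constants()`, not simulated.

## The generative observer

`simulate_responses()` draws Bernoulli responses with

    P("target") = Φ(−c_p(n) + d′_p(n) · X)

where X indicates that the queried object was a target and both linear
predictors carry population intercepts and load slopes, per-participant
Gaussian deviations on each, optional per-condition offsets, and optional
linear effects of a sudden-motion covariate.

The **bias convention** needs care: c is the distance of the decision
criterion from the mean of the distractor-evidence distribution, so the
false-alarm rate is Φ(−c), the hit rate Φ(d′ − c), and c > d′/2 makes the
observer miss-prone. This convention is the only one that reconciles the
reported sensitivity/bias pairs with the reported accuracies: at
(d′ = 3.08, c = 1.75) it gives hit rate ≈ 0.91, false-alarm rate ≈ 0.04
and accuracy ≈ 0.93 against the observed 95% at one target, and at
(d′ = 1.07, c = 0.86) accuracy ≈ 0.69 against the observed 73% at five
targets. Verbal glosses of the sign of "bias" conflict in the literature
this models; the package fixes the convention once, here and in
`per_participant_dprime()` (`c = −qnorm(FA)`), and never flips signs
silently.

Defaults (`population_params()`): α_d = 3.58, β_d = −0.50, α_c = 1.97,
β_c = −0.22 — the load-1 values 3.08/1.75 and per-target decrements
−0.50/−0.22 — with load entering uncentered as the raw number of targets,
so the slope reads "change per added target". The random-effect SDs are
not derivable from reported group-level numbers; σ_ad = 0.5, σ_bd = 0.1,
σ_ac = 0.3, σ_bc = 0.05 were fixed once as plausible for between-
participant accuracy SDs in the 7–16% range, and are the study conditions
for all recovery checks. With a nonzero cross-condition correlation ρ the
d′-intercept deviations are drawn per condition from the equicorrelated
multivariate Gaussian (eigendecomposition square root, so ρ = 1 is a valid
degenerate case). The sudden-motion covariate acts on both d′ and c
(γ_d, γ_c); the analysis side likewise enters covariates in both linear
predictors and reports separate Bayes factors, since the evidence tables
this mirrors examined both.

## Hierarchical probit inference

`fit_sdt_probit()` fits exactly the generative model: probit likelihood
with η = −c + d′·X, population terms (intercept, load, optional
deviation-coded condition offsets and condition×load interactions,
covariates) and four participant deviation blocks, N(0, 1) priors on
population coefficients and half-normal(0, 1) priors on the four
random-effect SDs.

The sampler is conjugate Gibbs with truncated-normal data augmentation:

1. latent evidence z_i ~ N(η_i, 1) truncated by the observed response
   (inverse-CDF draw, with the uniform clamped to [1e-14, 1 − 1e-14] so
   extreme linear predictors cannot produce infinities);
2. one joint multivariate-normal update of all coefficients and deviations
   from the normal equations (Cholesky solve; the cross-product matrix is
   precomputed once and only the prior diagonal changes per iteration);
3. a univariate slice-sampling update (stepping out + shrinkage) for each
   SD given its deviation block.

Priors on intercepts apply at mean-centered predictors — the convention of
standard multilevel-regression software — and draws are transformed back
to the uncentered parameterization afterwards; this matters because a
N(0, 1) prior applied at load 0 would shrink a load-1 sensitivity of ~3.6
noticeably, whereas at the design mean the same prior is weakly
informative. Deviation coding uses `contr.sum` over alphabetically ordered
condition levels.

Defaults are 4 chains × 1000 warmup + 1000 kept draws. Convergence is
checked with split-R̂ on the population parameters: above 1.05 the fit
raises a diagnostic error carrying the offending R̂ values; in (1.01,
1.05] it warns. The hard error sits at gross failure rather than at the
1.01 reporting bar because replicated recovery runs should not die on one
marginal chain; effective sample sizes (via `coda`) are always reported so
marginal fits are visible. A participant who is correct everywhere
triggers a perfect-separation warning and is handled by the priors. The
test suite cross-checks the sampler against an independent JAGS fit of the
identical model on one dataset (population posterior means within 0.15)
and against closed-form per-cell d′ when all random-effect SDs are zero.

Downstream summaries are linear combinations of draws:
`summarize_dprime_bias()` evaluates d′ and c at requested loads (warning
on extrapolation), and `contrast_conditions()` averages the two
load-specific values per condition within each draw before differencing,
so A − B = −(B − A) holds exactly per draw. `savage_dickey_bf()` computes
BF₁₀ as the N(0, 1) prior density at zero over a Gaussian-kernel estimate
(Silverman bandwidth) of the posterior density at zero, flagged unstable
when fewer than 50 draws fall within one bandwidth of zero — with a strong
effect the ratio is then a tail extrapolation, fine for "decisive" but not
for its digits. `apply_exclusion()` drops participants strictly below 50%
accuracy in the traditional two-target cell and flags (never silently
keeps) participants missing that cell. `per_participant_dprime()` uses the
1/(2N) continuity correction for hit or false-alarm rates of exactly 0
or 1.

## Prediction models and Bayesian R²

`fit_prediction_model()` regresses per-participant sensitivity (or bias)
in one condition on the same participant's value in another, a ±1-coded
load factor and their interaction, with a participant random intercept,
N(0, 1) coefficient priors and half-normal(0, 1) SD priors — the same
Gibbs machinery with a Gaussian likelihood and a slice update for the
residual SD. `bayesian_r2()` computes, per draw,
Var(fitted)/(Var(fitted) + Var(residual)) with *population-level* fitted
values and modeled residual variance σ_u² + σ_ε². Including the fitted
participant intercepts in the signal instead lets them absorb residual
noise (there are only two observations per intercept) and inflates R² by
roughly 0.1 at 52 participants, so the population-level form is the one
that calibrates against a generating signal-to-noise ratio.

A caveat the analysis scripts print: when the predictor is itself
estimated from ~46 binary trials per cell, errors-in-variables attenuate
the regression slope below the generating cross-participant relation. The
recovery tests therefore feed the model noise-free sensitivity tables;
the attenuation visible in `analysis/06_prediction.R` is a property of
two-stage estimation, not of the sampler.

## What the synthetic checks do and do not show

The synthetic observer draws from exactly the model the inference assumes,
so recovery and coverage results demonstrate correctness of the
implementation — likelihood, priors, sampler, summaries — under the study's
dimensions (10 participants × 138 trials; 50 × 92 × conditions). They do
not validate the model against real behaviour: human data bring lapses,
learning, serial dependence and motion-conditional strategies that the
generator deliberately omits (no reaction times, no lapse/guessing
mixture, no trial-order effects). Similarly, the fish-like generator
reproduces marginal motion statistics (gamma waits, dashes, waiting-time
fraction) but not schooling, interaction, occlusion by scenery, or any
directional structure.

Problem sizes in the test suite were chosen to make each check sharp at a
few minutes of total runtime: 20 replicates for CI coverage at the
10-participant scale (a 95% CI should cover ≥ 80% of 20 replicates under
small-sample tolerance), one 50-participant fit for contrast recovery, and
shortened chains (2 × 400 + 800) for replicated fits — the conjugate Gibbs
sampler's effective sample size per iteration is high enough that these
short chains keep split-R̂ under 1.01 in regular designs.

## Known limitations

* The segmentation artifacts above mean segmentation-based gamma fits are
  biased for slow or short dashes; use the schedule ground truth when the
  generator is yours, and treat fitted motion models from small arenas as
  descriptive.
* The ballistic collision rule is not momentum-conserving for oblique
  impacts (speed is pinned by design); it is a stimulus generator, not a
  physics engine.
* Savage–Dickey estimates degrade when the posterior leaves no mass near
  zero; the instability flag marks exactly that case.
* `fit_sdt_probit()` estimates no cross-condition correlation of
  participant effects (the generator can produce it; the model treats
  condition offsets as fixed and deviations as shared across conditions).
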