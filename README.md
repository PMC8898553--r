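# fishmot

Multiple object tracking (MOT) with naturalistic, fish-like motion:
stimulus simulation, experiment-design enumeration, a generative
signal-detection observer, and hierarchical Bayesian estimation of tracking
sensitivity and bias.

## The problem

In a MOT task observers covertly track a few cued targets among identical
distractors and, after the motion stops, judge whether one queried object
was a target. Laboratory MOT almost always uses constant-speed ballistic
circles; real creatures — for example fish in an aquarium — instead
alternate waiting at one spot with sudden dashes to a new location. This
package implements, as reusable and tested code, the full analysis chain
needed to study how those motion regimes affect tracking:

- **Motion layer.** Decompose object trajectories into *waiting* phases
  (all samples within a 60 px radius of an anchor) and *dash* phases, and
  fit gamma laws by maximum likelihood to waiting durations, dash distances
  and dash velocities (`segment_trajectory()`, `fit_gamma_mle()`,
  `fit_motion_model()`).
- **Stimulus simulators.** Ballistic motion at a constant 200 px/s with
  specular border reflection and elastic object bounces, and fish-like
  wait/dash motion driven by the fitted gamma laws, both inside an 800 px
  circular arena in a 960 × 600 px scene (`simulate_ballistic()`,
  `simulate_fishlike()`).
- **Experiment designs.** 23 scenes × loads {1, 3, 5} × {target,
  distractor} query = 138 trials for the single-condition experiment; 23 ×
  {2, 4} × 2 = 92 trials per condition for the three-condition experiment;
  six counterbalanced block orderings (`build_design_exp1()`,
  `build_design_exp2()`, `counterbalance_orders()`).
- **Generative observer.** Equal-variance SDT: the probability of calling
  the queried object a target is Φ(−c + d′·X), where X indicates a true
  target, d′ is sensitivity and c is the criterion measured from the
  distractor distribution mean (positive c = conservative, miss-prone).
  Both d′ and c are linear in tracking load with participant-level random
  intercepts and slopes, optional condition offsets and sudden-motion
  covariates (`population_params()`, `simulate_responses()`).
- **Inference.** The same model fitted by hierarchical Bayesian probit
  regression with N(0, 1) priors on population coefficients and
  half-normal(0, 1) priors on random-effect SDs, via a conjugate Gibbs
  sampler with truncated-normal data augmentation (`fit_sdt_probit()`),
  plus pooled condition contrasts, Savage–Dickey Bayes factors, the
  50%-accuracy exclusion rule, closed-form per-participant d′, multilevel
  Gaussian cross-condition prediction models and Bayesian R²
  (`contrast_conditions()`, `savage_dickey_bf()`, `apply_exclusion()`,
  `per_participant_dprime()`, `fit_prediction_model()`, `bayesian_r2()`).

The model, in the notation used throughout:

    P(response = "target") = Φ(η),   η = −c_p(n) + d′_p(n) · X
    d′_p(n) = α_d + δ_d[cond] + a_p + (β_d + b_p) · n + γ_d · (#sudden motions)
    c_p(n)  = α_c + δ_c[cond] + u_p + (β_c + v_p) · n + γ_c · (#sudden motions)

with a_p, b_p, u_p, v_p ~ N(0, σ²) participant deviations.

## Worked example

```r
library(fishmot)

# simulate ten observers doing the 138-trial design
pop  <- population_params()              # d' 3.08 at load 1, -0.50 per target
obs  <- sample_observers(pop, 10, seed = 1)
des  <- build_design_exp1(sprintf("v%02d", 1:23), seed = 1)
resp <- simulate_responses(obs, des, pop, seed = 2)

fit <- fit_sdt_probit(resp, chains = 4, warmup = 500, iter = 1000, seed = 7)
summarize_dprime_bias(fit, at_loads = c(1, 3, 5))
```

which prints (one simulated dataset, posterior mean and 95% CI):

```
  measure load condition  mean ci_low ci_high
1  dprime    1      <NA> 2.665  2.250   3.061
2    bias    1      <NA> 1.402  1.126   1.690
3  dprime    3      <NA> 1.943  1.501   2.341
4    bias    3      <NA> 1.123  0.800   1.429
5  dprime    5      <NA> 1.221  0.624   1.786
6    bias    5      <NA> 0.844  0.387   1.295
```

Sensitivity falls roughly linearly with load and the criterion relaxes —
the pattern the generative population (d′ = 3.08/2.08/1.07, bias =
1.75/1.30/0.86 at loads 1/3/5) encodes; any one 10-participant dataset
scatters around it. `savage_dickey_bf(fit, "d_load")` then quantifies the
evidence that the load slope differs from zero.

The `analysis/` directory holds the full workflow as numbered scripts —
`01_motion_model.R` (segmentation + gamma fits), `02_stimuli.R` (ballistic
and fish-like stimulus sets), `03_designs.R`, `04_simulate_observers.R`,
`05_sdt_inference.R` (probit fits, contrasts, exclusion), and
`06_prediction.R` (cross-condition prediction and Bayesian R²). Each is a
thin driver over the package functions and writes its tables under
`results/`. Run them in order from the repository root:

```sh
Rscript analysis/01_motion_model.R   # ... through 06
```

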