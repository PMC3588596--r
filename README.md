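# randinfer

Randomization-model inference for two-arm clinical trials.

## The problem

In a randomized trial the one source of randomness the analyst actually
controls is the treatment-assignment mechanism. The *randomization model*
takes that seriously: the patients, their entry order, their covariates and
their unit effects are fixed, and all probability statements come from
hypothetical rerandomizations of the trial's own assignment algorithm.
Under unit-treatment additivity the observations are

    y = y0 + tau * delta,

where `y0` is the fixed vector of unit effects, `tau` the treatment effect,
and `delta` the 0/1 vector of experimental assignments. With an `n x q`
covariate matrix `X` (intercept included) and residual-maker
`M = I - X (X'X)^{-1} X'`, the covariate-adjusted estimator is

    tau_hat = delta' M y / delta' M delta,

and with `V = Var(delta)` over rerandomizations its variance is
approximately

    Var(tau_hat) ~ y0' M V M y0 / tr(MV)^2,

estimated from data by

    var_hat = (y' M V M y - tau_hat^2 tr(MVMV)) / tr(MV)^2.

The quadratic form `delta' M delta` is ancillary and indexes conditional
inference; `V` comes from the design, exactly or by Monte Carlo.

The catch — and the reason this package exists — is that all of this
requires the *constant-probability condition*: every patient's
unconditional probability of experimental assignment must equal the planned
allocation fraction `p = r1/(r1+r2)`. Virtually all symmetric 1:1 designs
satisfy it. Popular dynamic randomization methods for *unequal* allocation
(threshold biased coins, marginal-balance minimization, the naive 2:1 urn
generalization) do **not**, and the estimator is then biased. `randinfer`
implements the designs, exposes their exact assignment probabilities, and
provides the estimation, testing, diagnostic and repair machinery.

## What is in the package

* **Designs** — `complete_design()`, `permuted_blocks_design()`,
  `biased_coin_design()`, `efron_design()`, `marginal_balance_design()`,
  `urn_design()`, `pocock_simon_design()`,
  `sequential_combine_design()` (+ `multiarm_blocks_design()` /
  `multiarm_complete_design()`), all exposing a uniform sequential
  assignment contract and samplers (`assign_sequence()`).
* **Exact engine** — `marginal_probs()` (forward dynamic programming over
  the design's state space), `limiting_prob()`, `enumerate_sequences()`,
  `assignment_moments()`, `conditional_moments()`.
* **Inference** — `randfit()` (formula + data fitting front end with
  `print`/`summary`/`coef`/`vcov`/`confint`/`residuals` methods), plus the
  building blocks `tau_hat()`, `var_approx()`, `var_hat()`,
  `conditional_var_hat()`, `conditional_bias()`, `unconditional_bias()`,
  `augment_repair()`, `z_test()`.
* **Linear-model comparison** — `lm_var_hat()`, `lm_var_expectation()`,
  `accidental_bias_form()`.
* **Randomization tests** — `randomization_test()` (unconditional or
  conditional on the ancillary bin), `null_moments()`.
* **Synthetic studies** — `unit_effects()`, `make_study_trial()` (a
  38-patient stratified 2:1 fixture), `run_study()`.

## A worked example

Why are 2:1 dynamic designs dangerous? Ask the exact engine:

```r
library(randinfer)
round(marginal_probs(biased_coin_design(c(2, 1)), 5), 3)
#> [1] 0.667 0.744 0.467 0.674 0.761
round(marginal_probs(marginal_balance_design(c(2, 1)), 5), 3)
#> [1] 0.667 0.433 0.807 0.881 0.342
round(as.numeric(limiting_prob(urn_design(2, 1, add_e_on_control = 2))), 3)
#> [1] 0.586
```

Every patient was supposed to have probability 2/3 of experimental
treatment; instead the probabilities oscillate between 0.34 and 0.88 (and
the naive urn drifts to 0.586). A design that *does* keep the condition is
a symmetric three-arm randomization with two arms combined:

```r
d <- sequential_combine_design(multiarm_blocks_design(3, 3), c(2, 1))
marginal_probs(d, 6)
#> [1] 0.6666667 0.6666667 0.6666667 0.6666667 0.6666667 0.6666667
```

Fitting the randomization model to a small blocked 1:1 trial:

```r
set.seed(7)
des   <- permuted_blocks_design(c(1, 1), 4)
delta <- assign_sequence(des, n = 24)
trial <- data.frame(delta = delta,
                    y = rnorm(24) + 1.5 * delta)
fit <- randfit(y ~ 1, trial, design = des, method = "exact")
summary(fit)
#> Randomization-model fit
#>   design: permuted blocks 1:1, block size 4
#>   tau_hat = 1.7558  (SE = 0.32531)
#>   z = 5.397, two-sided p = 6.768e-08 (tau0 = 0)
#>   95% CI: [1.1182, 2.3934]
#>   variance estimates: randomization 0.10583; linear model 0.14386
#>   E(delta_i) range: [0.500, 0.500]; target p = 0.500
```

`tau_hat` is the adjusted difference in means; the randomization-based
variance uses the exact `V` of the blocked design (here a little smaller
than the iid linear-model variance, as blocking suppresses the trend
exposure); the `E(delta_i)` line is the constant-probability diagnostic —
it would carry a warning flag for the 2:1 dynamic designs above, whose fix
is `augment_repair()`. A design-based p-value needs one more line:

```r
pr <- residual_projection(n = 24)
randomization_test(trial$y, delta, des, pr, reps = 1e4, seed = 1)$p.value
#> [1] 0.00029997
```

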