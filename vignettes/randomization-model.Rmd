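---
title: "Randomization-model inference: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomization-model inference: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randinfer)
```

## The model

`randinfer` performs design-based inference for two-arm trials. The
sampling frame is the randomization itself: patients, their entry order,
their covariates $X$ ($n \times q$, intercept in the column space, full
column rank) and their unit effects $y_0$ are all fixed; the only random
object is the assignment vector $\delta \in \{0,1\}^n$, distributed
according to the trial's sequential assignment algorithm. Unit-treatment
additivity links assignments to observations,
$$ y = y_0 + \tau\,\delta , $$
with a single scalar treatment effect $\tau$. No distributional assumption
is placed on $y_0$, and no relation between $y_0$ and $X$ is assumed.

Writing $M = I - X(X'X)^{-1}X'$ for the residual-maker, the normal
equations for $y$ on $[X, \delta]$ give the adjusted estimator
$$ \hat\tau = \frac{\delta' M y}{\delta' M \delta}. $$
All of its randomization-distribution properties flow from the first two
moments of $\delta$: the mean $E\delta$ and $V = \mathrm{Var}(\delta)$.

**The constant-probability condition.** The development requires
$E\delta = p\mathbf 1$ with $p = r_1/(r_1+r_2)$ the planned allocation
fraction — constant *unconditional* assignment probabilities, even though
the conditional ones move around to force balance. Under it (a first-order
ratio expansion, since both numerator and denominator of $\hat\tau$ are
random),
$$ \mathrm{Var}(\hat\tau) \approx \frac{y_0' M V M y_0}{\mathrm{tr}(MV)^2},
   \qquad
   \widehat{\mathrm{var}} = \frac{y' M V M y - \hat\tau^2\,
   \mathrm{tr}(MVMV)}{\mathrm{tr}(MV)^2}, $$
implemented as `var_approx()` and `var_hat()`. The variance approximation
depends on $y_0$ only through its residuals $My_0$ (covariate adjustment
helps exactly when it shrinks those residuals), and `var_hat()` is
approximately unbiased for it — the subtraction of
$\hat\tau^2\,\mathrm{tr}(MVMV)$ removes the "treatment sum of squares"
that would otherwise inflate the plug-in quadratic form. For symmetric 1:1
designs (those with $P(\delta = d) = P(\delta = \mathbf 1 - d)$ for all
$d$), $\hat\tau$ is *exactly* unbiased; the test suite verifies this by
full enumeration. A central-limit argument makes
$z = (\hat\tau - \tau_0)/\sqrt{\widehat{\mathrm{var}}}$ approximately
standard normal, giving the tests and intervals in `z_test()` and
`summary.randfit()`.

When a design violates $E\delta = p\mathbf 1$ the estimator is biased by,
to first order, $p' M y_0 / \mathrm{tr}(MV)$ with $p = E\delta$
(`unconditional_bias()`). Since the bias enters through $p'My_0$,
appending $p$ to the covariate matrix annihilates it; `augment_repair()`
does exactly that and the enumeration tests confirm the repair.

## The designs and their state abstractions

Every design is a sequential rule exposing (i) the conditional probability
of an experimental assignment given a *state*, (ii) the state transition,
and (iii) a hashable state key. The exact engine only ever sees this
contract, so exact computation extends automatically to any new design.
The states are the minimal sufficient statistics of each rule:

| design | state |
|---|---|
| complete | none |
| permuted blocks | per-stratum (remaining E slots, remaining slots) |
| threshold biased coin / Efron | arm counts $(n_e, n_c)$ |
| marginal balance | arm counts $(n_e, n_c)$ |
| urn | arm counts (the urn composition is a function of them) |
| Pocock–Simon | per-factor-level arm counts |
| arm-combining | the inner multi-arm design's state |

Two reconstruction choices deserve a note, because the defining formulas
are stated loosely in the minimization literature and the implementations
here are pinned by the exactly reproduced probability sequences instead:

* **Threshold biased coin (2:1).** The trigger is two-sided and
  *non-strict* on the allocation-normalized imbalance:
  $n_e/2 - n_c \le -1$ favors E with probability 0.9,
  $n_e/2 - n_c \ge +1$ favors C (probability 0.2 of E), anything else —
  including the first patient — uses $2/3$. This reproduces the exact
  sequence 0.667, 0.744, 0.467, 0.674, 0.761 and $P(\delta_{20}=1)=0.775$.
* **Marginal balance (2:1).** The rule compares the imbalance that *would
  result* from each hypothetical assignment of the current patient,
  $|(n_e+1)/2 - n_c|$ versus $|n_e/2 - (n_c+1)|$, favoring the assignment
  with the smaller post-assignment imbalance (0.9 / 0.2; ties and the
  first patient $2/3$). A pre-assignment comparison of $n_e/2$ with $n_c$
  looks superficially equivalent but is not: it matches the published
  sequence only through patient 3 and then diverges. The post-assignment
  form reproduces all of 0.433, 0.807, 0.881, 0.342 and
  $P(\delta_{20}=1)=0.340$, which is why it is the implementation.

The naive 2:1 urn (start 2 E, 1 C; add 2 E after a control assignment, 1 C
after an experimental one) drifts to a limiting probability of 0.586;
adding 4 E balls instead restores the limit $2/3$ — but note that even the
corrected urn has non-constant probabilities along the way (0.619, 0.641,
0.656, ...), so it satisfies the constant-probability condition only
asymptotically. The one construction that satisfies it *exactly* for
unequal allocation is `sequential_combine_design()`: randomize
symmetrically over $r_1 + r_2$ arms and pool $r_1$ of them into the
experimental arm; label symmetry of the inner design forces
$E\delta_i = p$ for every $i$. The inner design is pluggable; the default
used by the 38-patient fixture is stratified three-arm blocks of three.
For this design the binary assignment does not determine the inner arm, so
state transitions are *stochastic given $\delta_i$*; the engine carries a
distribution over states along each path, which handles this exactly.

## The exact engine

`marginal_probs()` is a forward pass: the state distribution is propagated
patient by patient, merging states by key, and
$P(\delta_i = 1) = \sum_s w_s\, \pi(s)$. Cost is linear in $n$ times the
number of reachable states (quadratic in $n$ for the count-state designs),
with a configurable cap (default $10^5$ states) beyond which the user is
directed to Monte Carlo. Mass conservation is asserted at every step at
$10^{-9}$. `limiting_prob()` iterates to a horizon (default 500) with a
convergence tolerance of $10^{-6}$ on successive probabilities and flags
non-convergence rather than guessing.

`enumerate_sequences()` produces every positive-probability assignment
sequence with its exact probability (depth-first, zero-probability
branches pruned, capped at $n \le 24$); it backs the exact moments, the
exact conditional moments, and the unbiasedness/symmetry tests.
`assignment_moments()` returns $E\delta$ and $V$ exactly (enumeration, or
the closed form $V = p(1-p)I$ for complete randomization) or by Monte
Carlo, where the samplers are vectorized per design family (block
permutations by ranking uniform keys; count-state rules advanced across
all replicates at once).

## Conditional inference

$\delta' M \delta$ is ancillary — for simple $X$ it is a function of
treatment-group sizes, e.g. $(1/n_0 + 1/n_1)^{-1}$ for intercept-only $X$
— and conditioning on it is the design-based analogue of conditioning on
observed sample sizes. `conditional_moments()` groups sequences by
$\delta' M \delta$ rounded to the nearest 0.2 (round-half-even; the bin
width matches the resolution at which these summaries are conventionally
reported and is adjustable) and returns per-bin masses, conditional means
$p_c$ and variances $V_c$.

For symmetric 1:1 designs $p_c \equiv 1/2$ and conditional inference is
clean. The conditional variance estimator implemented is
$$ \widehat{\mathrm{var}}_c = \frac{y' M V_c M y - \hat\tau^2\,
   \mathrm{tr}(MV_cMV_c)}{\mathrm{tr}(MV_c)^2 - \mathrm{tr}(MV_cMV_c)}. $$
The denominator correction (absent from the unconditional estimator) is
deliberate: within a bin the ancillary statistic is fixed, the estimator's
denominator is non-random, and with $Mp_c = 0$ one can show the estimator
above is *exactly* conditionally unbiased — the test suite checks this to
$10^{-8}$ by enumeration. Without the correction the estimator is low by
the factor $1 - \mathrm{tr}(MV_cMV_c)/\mathrm{tr}(MV_c)^2$, which for
vacuous conditioning (single bin) is the visible gap between
`conditional_var_hat()` and `var_hat()` at small $n$; the two agree as $n$
grows.

With unequal allocation, however, $p_c$ is typically *not* constant even
when $E\delta = p\mathbf 1$: in the 10-patient 2:1 blocks-of-6 example,
conditioning on $\delta'M\delta = 1.6$ forces patients 7–10 onto the
experimental arm ($p_c = 1$) while the complete-block patients stay at
$2/3$. The induced conditional bias is proportional to the covariance
between $p_c$ and $My_0$; `conditional_bias()` evaluates the first-order
form $p_c'My_0 / \mathrm{tr}(MV_c)$, and its normalized variant divides by
the conditional standard deviation $\sqrt{y_0'MV_cMy_0}/\mathrm{tr}(MV_c)$.
For the normalized-bias curves the unit-effect model is a linear trend in
entry order scaled to a stated $R^2$: the trend direction is the
unit-length centered order vector $z$, the noise variance solves
$R^2 = 1/(1 + (n-1)\sigma^2)$, and the expected normalized bias is
$p_c'Mz / \sqrt{z'MV_cMz + \sigma^2\,\mathrm{tr}(MV_c)}$ — positive in
low-ancillary bins and negative in high ones for the 38-patient fixture.

## Comparison with the population-model analysis

The ordinary linear model $y = X\beta + \delta\tau + \varepsilon$ with iid
errors yields the familiar variance estimate
$s^2/(\delta'M\delta)$ (`lm_var_hat()`). Its expectation over
rerandomizations, approximated by taking expectations of numerator and
denominator separately using only the first two assignment moments, is
$$ \frac{y_0'My_0 - y_0'MVMy_0/\mathrm{tr}(MV)}{(n-q-1)\,
   \mathrm{tr}(MV)} $$
(`lm_var_expectation()`); under additivity and constant probabilities the
treatment effect cancels from this expression, so it is reported without a
$\tau$ argument. Monte Carlo validation shows agreement with the mean of
`lm_var_hat()` within a fraction of a percent at $n = 40$. The comparison
with the randomization variance reproduces the classic orderings: equal in
expectation for patternless unit effects (both reduce to
$\sigma^2/\mathrm{tr}(MV)$); linear model larger under low-frequency
trends; smaller under high-frequency alternation. The driver is the
accidental-bias quadratic form $z'MVMz$ (`accidental_bias_form()`). Under
complete randomization ($V = p(1-p)I$) the randomization and linear-model
estimators agree up to the $(n-q-1)$ versus $\mathrm{tr}(MV)/p(1-p)$
divisor — an $O(1/n)$ discrepancy, which is how the equivalence is tested
(5% at $n = 200$) rather than as an exact identity.

## Randomization tests

`randomization_test()` rerandomizes the design over the fixed patient
order, holding $y$ fixed, and compares the observed $\hat\tau$ with the
replicate distribution. P-values use the add-one convention
$(\#\{\text{as extreme}\}+1)/(R+1)$, which keeps the test valid at any
$R$; two-sided extremity is measured around the replicate mean, so the
test remains size-correct even for designs with $E\delta \ne p\mathbf 1$
(their reference distribution is simply not centered at zero). Replicates
with $\delta'M\delta = 0$ are skipped and counted. The conditional variant
keeps only replicates in the observed ancillary bin, doubling the bin
width (with a warning) while occupancy is below `min_bin` (default 200).
The null-distribution moments (`null_moments()`) are mean
$p'My/\mathrm{tr}(MV)$ and variance $y'MVMy/\mathrm{tr}(MV)^2$; the null
variance exceeds `var_hat()` by $\hat\tau^2\,\mathrm{tr}(MVMV)/
\mathrm{tr}(MV)^2$, the removed treatment sum of squares.

## The synthetic generator and the bundled studies

`unit_effects()` produces the fixed unit-effect vectors used throughout:
iid, linear trend, low-frequency (half-cycle sinusoid over the enrollment
window), and high-frequency (alternating signs). The structured patterns
are built so the regression of $y_0$ on the pattern attains the requested
$R^2$ *exactly* (deterministic component plus noise residualized on it and
rescaled) and the sample variance equals `sigma2` exactly; this removes
one layer of simulation noise from every downstream check. What the
generator emulates is temporal structure in patient outcomes over
enrollment; what it does not emulate is everything else about real trials
— measurement error models, covariate-outcome relationships beyond the
stratum effects, missingness, or non-additive treatment effects — so
passing tests certify the randomization-theoretic properties, not clinical
realism.

`make_study_trial()` builds the 38-patient stratified 2:1 fixture: two
binary factors with cell counts 10, 8, 11, 9; entry order drawn once from
a seed and then held fixed (the order is synthetic — only the cell
composition is specified, and the expected ancillary value
$\mathrm{tr}(MV) = 8.337$ is invariant to the order, though
patient-by-patient conditional curves are not); $X$ = intercept + two
main effects; designs = stratified blocks of six, and the arm-combining
design with stratified three-arm blocks of three (the inner method is a
package choice — any symmetric three-arm rule would preserve
$E\delta = \tfrac23\mathbf 1$).

Problem sizes for the bundled studies were chosen to make every check
exact where enumeration is feasible ($n \le 10$–$12$) and to keep Monte
Carlo noise comfortably below the asserted tolerances elsewhere:
$2\times10^5$ rerandomizations for the ancillary distribution
(standard error of the mean $\approx 0.001$), $10^5$ for variance-
unbiasedness and conditional-bias curves, $2\times10^4$ for coverage.
`run_study()` packages four end-to-end studies (`dynamic_probs`,
`conditional_bias`, `variance_compare`, `coverage`) with CSV output.

## Numerical choices and limitations

* Degenerate assignments ($\delta'M\delta = 0$, e.g. everyone on one arm
  under complete randomization) are errors in estimation and skipped-and-
  counted in tests; conditional expectations are taken over the
  non-degenerate set.
* `var_hat()` and `conditional_var_hat()` floor negative values at zero
  and flag them (attribute `floored`) — the subtraction can go negative in
  small samples; an error would be worse than a conservative zero.
* Rank decisions use QR with tolerance $10^{-10}$; rank-deficient $X$ is
  an error naming the collinear columns, not a silent generalized inverse.
* The constant-probability diagnostic flags
  $\max_i |E\delta_i - p| > 0.005$ (exact probabilities) or three Monte
  Carlo standard errors.
* Monte Carlo moments use the sample covariance with its usual $R-1$
  divisor; at the replicate counts used the difference is immaterial.
* Scope: two arms, continuous endpoints, constant $\tau$. More than two
  treatments, binary or time-to-event endpoints, and response-adaptive
  randomization are out of scope; heterogeneous effects are touched only
  by the remark that $\hat\tau$ then tracks an average effect when the
  diagonal of $VM$ is near-constant.
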