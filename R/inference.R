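## randomization-model estimation: the adjusted treatment-effect estimator
## tau_hat = delta'My / delta'Mdelta, its variance under rerandomization,
## and bias diagnostics for designs whose unconditional assignment
## probabilities are not constant

#' Randomization-model treatment-effect estimator
#'
#' The covariate-adjusted estimator
#' `tau_hat = delta' M y / delta' M delta`, i.e. the coefficient of the
#' assignment indicator in the least-squares fit of `y` on `[X, delta]`.
#' Under unit-treatment additivity (`y = y0 + tau * delta`) and a design
#' with constant unconditional assignment probability it is approximately
#' unbiased over rerandomizations, and exactly unbiased for symmetric 1:1
#' designs.
#'
#' @param y response vector.
#' @param delta 0/1 assignment vector.
#' @param projection a [`projection`][residual_projection].
#' @return The scalar estimate.
#' @export
tau_hat <- function(y, delta, projection) {
  a <- ancillary(projection, delta)
  if (a < 1e-12)
    stop("degenerate assignment: delta' M delta = 0")
  drop(crossprod(delta, projection$M %*% y)) / a
}

#' Rerandomization variance of the treatment-effect estimator
#'
#' `var_approx()` evaluates the first-order variance approximation
#' `Var(tau_hat) ~= y0' M V M y0 / tr(MV)^2`, a quadratic form in the
#' residuals of the unit effects after regression on `X` (it is invariant
#' to adding any `X b` to `y0`). `var_hat()` is its estimable counterpart
#' from observed data,
#' `(y' M V M y - tau_hat^2 tr(MVMV)) / tr(MV)^2`,
#' an approximately unbiased estimator of the variance; a negative value
#' (a small-sample artifact of the subtraction) is floored at zero and
#' flagged via the `"floored"` attribute.
#'
#' @param y0 unit-effect vector (fixed patient effects absent treatment).
#' @param y observed response vector.
#' @param delta 0/1 assignment vector.
#' @param projection a [`projection`][residual_projection].
#' @param moments an [`assignment_moments`][assignment_moments] object for
#'   the trial's randomization design.
#' @return A scalar variance (approximation or estimate).
#' @export
var_approx <- function(y0, projection, moments) {
  M <- projection$M; V <- moments$V
  tmv <- .trAB(M, V)
  if (tmv <= 0) stop("tr(MV) must be positive")
  a <- M %*% y0
  drop(crossprod(a, V %*% a)) / tmv^2
}

#' @rdname var_approx
#' @export
var_hat <- function(y, delta, projection, moments) {
  M <- projection$M; V <- moments$V
  tmv <- .trAB(M, V)
  if (tmv <= 0) stop("tr(MV) must be positive")
  MV <- M %*% V
  trW <- sum(MV * t(MV))          # tr(MVMV)
  th <- tau_hat(y, delta, projection)
  a <- M %*% y
  est <- (drop(crossprod(a, V %*% a)) - th^2 * trW) / tmv^2
  if (est < 0) structure(0, floored = TRUE) else structure(est, floored = FALSE)
}

#' Conditional variance estimator given the ancillary statistic
#'
#' Variance estimation conditional on the realized value of
#' `delta' M delta`: the conditional moments `p_c`, `V_c` of the bin
#' containing the realized ancillary value replace the unconditional `V`.
#' The estimator
#' `(y' M V_c M y - tau_hat^2 tr(M V_c M V_c)) / (tr(M V_c)^2 - tr(M V_c M V_c))`
#' is exactly conditionally unbiased for symmetric 1:1 designs whose bins
#' hold the ancillary value fixed (the denominator correction is what makes
#' the unbiasedness exact rather than first-order). Negative values are
#' floored at zero and flagged.
#'
#' @inheritParams var_approx
#' @param cond a [`conditional_moments`][conditional_moments] object.
#' @return The scalar estimate, with attributes `bin` (the bin used) and
#'   `floored`.
#' @export
conditional_var_hat <- function(y, delta, projection, cond) {
  a_obs <- ancillary(projection, delta)
  ctr <- .bin_values(a_obs, cond$bin_width)
  j <- which(abs(cond$bins - ctr) < cond$bin_width / 4)
  if (!length(j)) {
    j <- which.min(abs(cond$bins - a_obs))
    warning(sprintf(
      "realized ancillary value %.3g falls in an empty bin; using nearest populated bin %.3g",
      a_obs, cond$bins[j]))
  }
  Vc <- cond$V_c[[j]]
  M <- projection$M
  tmv <- .trAB(M, Vc)
  MV <- M %*% Vc
  trW <- sum(MV * t(MV))
  den <- tmv^2 - trW
  if (den <= 0) stop("degenerate conditional moments in the selected bin")
  th <- tau_hat(y, delta, projection)
  a <- M %*% y
  est <- (drop(crossprod(a, Vc %*% a)) - th^2 * trW) / den
  structure(max(est, 0), bin = cond$bins[j], floored = est < 0)
}

#' Conditional bias of the estimator given the ancillary statistic
#'
#' With unequal allocation the conditional assignment probabilities `p_c`
#' vary across patients even when the unconditional ones are constant, and
#' the treatment-effect estimator acquires a conditional bias proportional
#' to the covariance between `p_c` and the unit-effect residuals `M y0`:
#' first order, `bias(c) ~= p_c' M y0 / tr(M V_c)`. With
#' `normalized = TRUE` the bias is divided by the conditional standard
#' deviation `sqrt(y0' M V_c M y0) / tr(M V_c)`.
#'
#' @param p_c conditional mean assignment vector for the bin.
#' @param y0 unit-effect vector.
#' @inheritParams var_approx
#' @param V_c conditional variance matrix for the bin.
#' @param normalized divide by the conditional standard deviation of the
#'   estimator?
#' @return The scalar (normalized) conditional bias.
#' @export
conditional_bias <- function(p_c, y0, projection, V_c, normalized = FALSE) {
  M <- projection$M
  a <- M %*% y0
  num <- drop(crossprod(p_c, a))
  if (normalized) {
    s2 <- drop(crossprod(a, V_c %*% a))
    if (s2 <= 0) return(0)
    num / sqrt(s2)
  } else num / .trAB(M, V_c)
}

#' Unconditional bias when assignment probabilities are not constant
#'
#' When `E(delta) = p_vec` differs from a constant vector, the estimator is
#' biased; to first order the bias is `p_vec' M y0 / tr(MV)`, a function of
#' the correlation between the assignment-probability profile and the
#' unit-effect residuals. It vanishes when `p_vec` is constant (since
#' `M 1 = 0`).
#'
#' @param p_vec vector of unconditional assignment probabilities, e.g. from
#'   [marginal_probs()].
#' @inheritParams var_approx
#' @return The scalar first-order bias.
#' @export
unconditional_bias <- function(p_vec, y0, projection, moments) {
  M <- projection$M
  drop(crossprod(p_vec, M %*% y0)) / .trAB(M, moments$V)
}

#' Covariate augmentation repair for non-constant assignment probabilities
#'
#' For a design with `E(delta) = p_vec` not constant, augmenting the
#' covariate matrix with `p_vec` removes the leading bias term (the bias is
#' a function of `p_vec' M y0`, which the augmented projection annihilates).
#' If `p_vec` already lies in the column space of `X` (in particular, if it
#' is constant) the projection is returned unchanged with a warning.
#'
#' @inheritParams unconditional_bias
#' @param projection the [`projection`][residual_projection] to augment.
#' @param tol collinearity tolerance.
#' @return A new `"projection"` with `p_vec` appended as a covariate.
#' @export
augment_repair <- function(projection, p_vec, tol = 1e-8) {
  r <- projection$M %*% p_vec
  if (sum(r^2) < tol * projection$n) {
    warning("'p_vec' is already in the column space of X; nothing to repair")
    return(projection)
  }
  residual_projection(x = cbind(projection$X, p = p_vec))
}

#' Normal-approximation test and confidence interval
#'
#' Computes `z = (tau_hat - tau0) / sqrt(variance)`, its two-sided normal
#' p-value, and the Wald interval `tau_hat +/- z_{alpha/2} sqrt(variance)`,
#' relying on the asymptotic normality of the randomization-model estimator.
#'
#' @param estimate the treatment-effect estimate.
#' @param variance its estimated variance (e.g. [var_hat()]).
#' @param tau0 null value.
#' @param level confidence level.
#' @return List with `z`, `p.value`, and `ci`.
#' @export
z_test <- function(estimate, variance, tau0 = 0, level = 0.95) {
  if (variance <= 0) stop("variance must be positive for the z test")
  se <- sqrt(variance)
  z <- (estimate - tau0) / se
  crit <- stats::qnorm(1 - (1 - level) / 2)
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)),
       ci = c(lower = estimate - crit * se, upper = estimate + crit * se))
}
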