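## comparison of the randomization-model variance with the ordinary
## population-model (iid errors) linear-model variance estimator

#' Linear-model variance estimate of the treatment coefficient
#'
#' The ordinary least-squares variance estimate for the treatment
#' coefficient in the population model `y = X beta + delta tau + eps` with
#' iid errors: `s^2 / (delta' M delta)`, where `s^2` is the residual mean
#' square from the fit on `[X, delta]` (residual degrees of freedom
#' `n - q - 1`).
#'
#' @inheritParams var_approx
#' @return The scalar variance estimate.
#' @export
lm_var_hat <- function(y, delta, projection) {
  n <- projection$n; q <- projection$q
  if (n <= q + 1) stop("no residual degrees of freedom")
  a <- ancillary(projection, delta)
  if (a < 1e-12) stop("degenerate assignment: delta' M delta = 0")
  My <- projection$M %*% y
  rss <- drop(crossprod(y, My)) - drop(crossprod(delta, My))^2 / a
  (max(rss, 0) / (n - q - 1)) / a
}

#' Randomization expectation of the linear-model variance estimate
#'
#' Approximates the expectation, over rerandomizations of the design, of
#' the linear-model variance estimate [lm_var_hat()], by taking
#' expectations of its numerator and denominator separately (a
#' ratio-of-expectations approximation using the first two assignment
#' moments):
#' `(y0' M y0 - y0' M V M y0 / tr(MV)) / ((n - q - 1) tr(MV))`.
#' Under unit-treatment additivity and a constant-probability design the
#' treatment effect cancels from this approximation, so only the unit
#' effects enter. Comparing it with the randomization variance
#' [var_approx()] reproduces the classic orderings: the two agree for
#' patternless (iid) unit effects, the linear model overstates the variance
#' under low-frequency trends, and understates it under high-frequency
#' alternation.
#'
#' @inheritParams var_approx
#' @return The scalar approximation.
#' @export
lm_var_expectation <- function(y0, projection, moments) {
  M <- projection$M; V <- moments$V
  n <- projection$n; q <- projection$q
  if (n <= q + 1) stop("no residual degrees of freedom")
  tmv <- .trAB(M, V)
  a <- M %*% y0
  (drop(crossprod(y0, a)) - drop(crossprod(a, V %*% a)) / tmv) /
    ((n - q - 1) * tmv)
}

#' Accidental-bias quadratic form
#'
#' Expected squared bias (up to a constant) of the treatment-effect
#' estimator induced by an unmodeled unit-length covariate `z`:
#' `z' M V M z`. For complete randomization it reduces to
#' `p (1-p) z' M z`; designs that balance assignments over time (e.g.
#' permuted blocks) suppress the exposure of smooth trends and give smaller
#' values for trend-like `z`.
#'
#' @param z covariate direction; normalized to unit length internally.
#' @inheritParams var_approx
#' @return The scalar quadratic form.
#' @export
accidental_bias_form <- function(z, projection, moments) {
  z <- z / sqrt(sum(z^2))
  a <- projection$M %*% z
  drop(crossprod(a, moments$V %*% a))
}
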