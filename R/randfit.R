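#' Fit the randomization model to trial data
#'
#' The main model-fitting interface: estimates the treatment effect of a
#' two-arm trial under the randomization model, in which patients, their
#' entry order, covariates and unit effects are fixed and all randomness
#' comes from the treatment-assignment mechanism. Given the observed
#' assignment vector and the trial's randomization design, `randfit()`
#' computes the covariate-adjusted estimator `tau_hat`, its
#' randomization-based variance estimate (and, optionally, the estimate
#' conditional on the realized ancillary statistic `delta' M delta`), the
#' ordinary linear-model variance estimate for comparison, a normal
#' approximation test and confidence interval, and a diagnostic for whether
#' the design satisfies the constant-assignment-probability requirement
#' `E(delta) = p 1` (when it does not, the estimator is biased and the fit
#' carries a warning flag).
#'
#' @param formula model formula `y ~ covariates`; the right-hand side
#'   defines the covariate matrix `X` (an intercept is always included).
#' @param data data frame with the response, covariates, and (unless given
#'   explicitly) a `delta` column of 0/1 assignments, one row per patient in
#'   randomization order.
#' @param design the trial's [`rand_design`][complete_design].
#' @param delta assignment vector; defaults to `data$delta`.
#' @param strata per-patient stratum labels used by the design (vector,
#'   data frame, or `NULL`).
#' @param moments optional precomputed
#'   [`assignment_moments`][assignment_moments]; computed from the design
#'   otherwise.
#' @param method,reps,seed passed to [assignment_moments()] when `moments`
#'   is not supplied.
#' @param conditional also compute the variance estimate conditional on the
#'   realized ancillary bin?
#' @param bin_width ancillary grouping resolution for conditional
#'   inference.
#' @param tau0 null value for the z test.
#' @param level confidence level.
#' @return An object of class `"randfit"` with `print()`, `summary()`,
#'   `coef()`, `vcov()`, `confint()`, `fitted()` and `residuals()` methods.
#' @examples
#' set.seed(7)
#' d <- permuted_blocks_design(c(1, 1), 4)
#' delta <- assign_sequence(d, n = 24)
#' y0 <- rnorm(24)
#' trial <- data.frame(y = y0 + 1.5 * delta, delta = delta)
#' fit <- randfit(y ~ 1, trial, design = d)
#' summary(fit)
#' @export
randfit <- function(formula, data, design, delta = NULL, strata = NULL,
                    moments = NULL, method = c("auto", "exact", "monte-carlo"),
                    reps = 1e5, seed = NULL, conditional = FALSE,
                    bin_width = 0.2, tau0 = 0, level = 0.95) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  proj <- residual_projection(formula = stats::delete.response(
    stats::terms(formula)), data = data)
  n <- proj$n
  if (is.null(delta)) delta <- data$delta
  if (is.null(delta)) stop("no 'delta' column in 'data' and none supplied")
  delta <- as.integer(delta)
  stopifnot(length(delta) == n, all(delta %in% 0:1))

  if (is.null(moments))
    moments <- assignment_moments(design, n, strata, method = method,
                                  reps = reps, seed = seed)
  th <- tau_hat(y, delta, proj)
  vr <- var_hat(y, delta, proj, moments)
  vlm <- lm_var_hat(y, delta, proj)

  # constant-probability diagnostic: exact marginal probabilities where the
  # DP is feasible, Monte Carlo means otherwise
  p_vec <- tryCatch(marginal_probs(design, n, strata),
                    error = function(e) moments$mean)
  p <- design$alloc$p
  tol <- if (moments$source == "exact" || !is.null(attr(p_vec, "exact")))
    0.005 else 3 * sqrt(p * (1 - p) / max(moments$reps, 1))
  bias_flag <- max(abs(p_vec - p)) > max(tol, 0.005)

  cond <- NULL; v_cond <- NULL
  if (conditional) {
    cm_method <- if (moments$source == "exact") "exact" else "monte-carlo"
    cond <- conditional_moments(design, n, strata, projection = proj,
                                bin_width = bin_width, method = cm_method,
                                reps = reps, seed = seed)
    v_cond <- conditional_var_hat(y, delta, proj, cond)
  }
  zt <- z_test(th, as.numeric(vr), tau0 = tau0, level = level)

  structure(list(
    coefficients = c(tau = th), var_rand = vr,
    var_rand_conditional = v_cond, var_lm = vlm,
    z = zt$z, p.value = zt$p.value, ci = zt$ci, level = level, tau0 = tau0,
    bias = list(flag = bias_flag, p_vec = p_vec, p = p),
    projection = proj, moments = moments, conditional = cond,
    design = design, y = y, delta = delta, n = n,
    call = match.call()), class = "randfit")
}

#' @export
print.randfit <- function(x, ...) {
  cat("Randomization-model fit\n")
  cat("  design:", x$design$name, "\n")
  cat(sprintf("  tau_hat = %.5g  (SE = %.5g)\n",
              x$coefficients[["tau"]], sqrt(as.numeric(x$var_rand))))
  if (x$bias$flag)
    cat("  WARNING: E(delta) deviates from the allocation fraction;",
        "estimator is biased (consider augment_repair)\n")
  invisible(x)
}

#' @export
summary.randfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.randfit")
}

#' @export
print.summary.randfit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  z = %.4g, two-sided p = %.4g (tau0 = %g)\n",
              f$z, f$p.value, f$tau0))
  cat(sprintf("  %g%% CI: [%.5g, %.5g]\n", 100 * f$level,
              f$ci[["lower"]], f$ci[["upper"]]))
  cat(sprintf("  variance estimates: randomization %.5g; linear model %.5g\n",
              as.numeric(f$var_rand), f$var_lm))
  if (!is.null(f$var_rand_conditional))
    cat(sprintf("  conditional variance (ancillary bin %.3g): %.5g\n",
                attr(f$var_rand_conditional, "bin"),
                as.numeric(f$var_rand_conditional)))
  rng <- range(f$bias$p_vec)
  cat(sprintf("  E(delta_i) range: [%.3f, %.3f]; target p = %.3f%s\n",
              rng[1], rng[2], f$bias$p,
              if (f$bias$flag) "  ** constant-probability condition violated **"
              else ""))
  invisible(x)
}

#' @export
coef.randfit <- function(object, ...) object$coefficients

#' @export
vcov.randfit <- function(object, ...)
  matrix(as.numeric(object$var_rand), 1, 1, dimnames = list("tau", "tau"))

#' @export
confint.randfit <- function(object, parm = "tau", level = NULL, ...) {
  if (is.null(level)) level <- object$level
  zt <- z_test(object$coefficients[["tau"]], as.numeric(object$var_rand),
               tau0 = object$tau0, level = level)
  matrix(zt$ci, 1, 2,
         dimnames = list("tau", sprintf("%.1f %%",
                                        100 * c((1 - level) / 2,
                                                1 - (1 - level) / 2))))
}

#' @export
fitted.randfit <- function(object, ...) object$y - stats::residuals(object)

#' @export
residuals.randfit <- function(object, ...) {
  # residuals from the least-squares fit of y on [X, delta]
  M <- object$projection$M
  drop(M %*% object$y) -
    object$coefficients[["tau"]] * drop(M %*% object$delta)
}
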