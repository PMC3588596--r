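#' Monte Carlo randomization test of no treatment effect
#'
#' Tests the sharp null hypothesis that treatment has no effect in any
#' patient by rerandomizing the design over the patients in their fixed
#' entry order and recomputing the treatment-effect estimator for each
#' replicate assignment, holding the observed responses fixed. The p-value
#' uses the add-one convention `(count + 1) / (reps + 1)`, which keeps the
#' test valid. The conditional variant restricts the reference set to
#' replicates whose ancillary statistic falls in the bin (nearest
#' `bin_width`) of the observed `delta' M delta`, widening the bin when it
#' is under-populated.
#'
#' Because the test is built from the design's own randomization
#' distribution, its size is controlled by construction even for designs
#' whose unconditional assignment probabilities are not constant (for
#' those, the reference distribution is simply not centered at zero, and
#' the two-sided p-value is computed around the replicate mean).
#'
#' @inheritParams randfit
#' @param y response vector.
#' @param delta observed 0/1 assignment vector.
#' @param projection a [`projection`][residual_projection].
#' @param reps number of rerandomizations.
#' @param sided `"two"` or `"one"` (one-sided: large positive effects).
#' @param conditional condition on the observed ancillary bin?
#' @param min_bin minimum replicates required in the conditional bin before
#'   widening.
#' @param moments optional [`assignment_moments`][assignment_moments]; when
#'   supplied, the theoretical null-distribution moments from
#'   [null_moments()] are attached to the result.
#' @param keep_replicates store the replicate estimates (for plotting)?
#' @return An object of class `"rand_test"`: list with the observed
#'   estimate, p-values, number of replicates used, empirical null mean and
#'   variance, the conditional bin (if any), and the count of degenerate
#'   replicates skipped.
#' @examples
#' set.seed(11)
#' d <- complete_design(c(1, 1))
#' delta <- assign_sequence(d, n = 30)
#' y <- rnorm(30) + 2 * delta
#' pr <- residual_projection(n = 30)
#' randomization_test(y, delta, d, pr, reps = 2000)
#' @export
randomization_test <- function(y, delta, design, projection, strata = NULL,
                               reps = 1e4, sided = c("two", "one"),
                               conditional = FALSE, bin_width = 0.2,
                               min_bin = 200, moments = NULL, seed = NULL,
                               keep_replicates = FALSE) {
  sided <- match.arg(sided)
  n <- projection$n
  stopifnot(length(y) == n, length(delta) == n)
  th <- tau_hat(y, delta, projection)

  sl <- .norm_strata(strata, n)
  D <- .with_seed(seed, rand_draws(design, sl, as.integer(reps)))
  a_r <- ancillary(projection, D)
  ok <- a_r > 1e-12
  skipped <- sum(!ok)
  tau_r <- (colSums(D * drop(projection$M %*% y)))[ok] / a_r[ok]
  a_r <- a_r[ok]

  bin_used <- NA_real_; bw <- bin_width
  if (conditional) {
    ctr <- .bin_values(ancillary(projection, delta), bw)
    keep <- abs(a_r - ctr) <= bw / 2
    while (sum(keep) < min_bin && bw < 2 * (max(a_r) - min(a_r) + bin_width)) {
      bw <- 2 * bw
      ctr <- .bin_values(ancillary(projection, delta), bw)
      keep <- abs(a_r - ctr) <= bw / 2
      warning(sprintf("conditional bin under-populated; widened to %.3g", bw))
    }
    tau_r <- tau_r[keep]
    bin_used <- ctr
  }
  R <- length(tau_r)
  null_mean <- mean(tau_r)
  eps <- 1e-12 * (1 + abs(th))  # guard against ties at machine precision
  p_one <- (sum(tau_r >= th - eps) + 1) / (R + 1)
  p_two <- (sum(abs(tau_r - null_mean) >= abs(th - null_mean) - eps) + 1) /
    (R + 1)

  nm <- if (!is.null(moments))
    null_moments(y, projection, moments) else NULL

  structure(list(
    statistic = th, reps_used = R, skipped = skipped,
    p.value = if (sided == "two") p_two else p_one,
    p_one_sided = p_one, p_two_sided = p_two, sided = sided,
    null_mean = null_mean, null_var = stats::var(tau_r),
    null_moments = nm,
    conditional = conditional, bin = bin_used, bin_width = bw,
    replicates = if (keep_replicates) tau_r else NULL),
    class = "rand_test")
}

#' @export
print.rand_test <- function(x, ...) {
  cat(sprintf("Randomization test (%s-sided%s): %d replicates\n",
              x$sided,
              if (x$conditional)
                sprintf(", conditional on ancillary bin %.3g", x$bin)
              else "", x$reps_used))
  cat(sprintf("  observed tau_hat = %.5g\n", x$statistic))
  cat(sprintf("  p = %.4g  (one-sided %.4g, two-sided %.4g)\n",
              x$p.value, x$p_one_sided, x$p_two_sided))
  cat(sprintf("  replicate mean %.4g, variance %.5g\n",
              x$null_mean, x$null_var))
  if (!is.null(x$null_moments))
    cat(sprintf("  theoretical null mean %.4g, variance %.5g\n",
                x$null_moments$mean, x$null_moments$variance))
  if (x$skipped > 0)
    cat(sprintf("  (%d degenerate replicates skipped)\n", x$skipped))
  invisible(x)
}

#' @describeIn randomization_test Histogram of the replicate estimates with
#'   the observed value marked (requires `keep_replicates = TRUE`).
#' @param x a `"rand_test"` object.
#' @param ... passed to [graphics::hist()].
#' @export
plot.rand_test <- function(x, ...) {
  if (is.null(x$replicates))
    stop("rerun with keep_replicates = TRUE to plot")
  graphics::hist(x$replicates, main = "Randomization distribution",
                 xlab = "replicate treatment-effect estimate", ...)
  graphics::abline(v = x$statistic, col = 2, lwd = 2)
  invisible(x)
}

#' Moments of the null randomization distribution
#'
#' First two moments of the treatment-effect estimator over
#' rerandomizations when treatment has no effect (`y = y0`): the mean is
#' `p_vec' M y / tr(MV)` -- zero for constant-probability designs -- and the
#' variance is `y' M V M y / tr(MV)^2`. The null variance exceeds the
#' data-based estimate [var_hat()] by approximately
#' `tau^2 tr(MVMV) / tr(MV)^2`, the "sum of squares for treatment" removed
#' by the estimator.
#'
#' @inheritParams var_approx
#' @param y response vector (under the null, the unit effects).
#' @return List with `mean` and `variance`.
#' @export
null_moments <- function(y, projection, moments) {
  M <- projection$M; V <- moments$V
  tmv <- .trAB(M, V)
  a <- M %*% y
  list(mean = drop(crossprod(moments$mean, a)) / tmv,
       variance = drop(crossprod(a, V %*% a)) / tmv^2)
}
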