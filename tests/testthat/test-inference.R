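test_that("tau_hat is the adjusted least-squares treatment coefficient", {
  set.seed(31)
  n <- 12
  df <- data.frame(s = factor(rep(c("a", "b"), 6)), x = rnorm(n))
  pr <- residual_projection(~ s + x, data = df)
  delta <- rep(c(1L, 0L), c(7, 5))[sample(n)]
  y <- rnorm(n) + 0.8 * delta

  fit <- lm(y ~ s + x + delta, data = df)
  expect_equal(tau_hat(y, delta, pr), unname(coef(fit)["delta"]),
               tolerance = 1e-10)

  # null unit effects recover tau exactly
  expect_equal(tau_hat(1.7 * delta, delta, pr), 1.7, tolerance = 1e-10)

  # intercept-only adjustment is the difference in group means
  pr0 <- residual_projection(n = n)
  expect_equal(tau_hat(y, delta, pr0),
               mean(y[delta == 1]) - mean(y[delta == 0]), tolerance = 1e-10)

  expect_error(tau_hat(y, rep(1L, n), pr0), "degenerate")
})

test_that("tau_hat is exactly unbiased for symmetric 1:1 designs", {
  pr <- residual_projection(n = 6)
  y0 <- c(0.3, -1.2, 0.5, 2.0, -0.7, 0.9)
  tau <- 2
  for (d in list(efron_design(), permuted_blocks_design(c(1, 1), 2))) {
    e <- enum_nondegenerate(enumerate_sequences(d, 6), pr)
    th <- apply(e$delta, 1, function(del)
      tau_hat(y0 + tau * del, del, pr))
    expect_equal(sum(th * e$prob), tau, tolerance = 1e-10)
  }
})

test_that("var_approx is the variance of the linearized estimator", {
  n <- 4
  pr <- residual_projection(n = n)
  d <- complete_design(c(1, 1))
  mom <- assignment_moments(d, n)
  y0 <- c(0, 0, 1, 1)

  # exhaustive oracle: Var of delta' M y0 / tr(MV) over all 16 assignments
  e <- enumerate_sequences(d, n)
  stat <- apply(e$delta, 1, function(del)
    sum(del * drop(pr$M %*% y0))) / sum(pr$M * mom$V)
  mu <- sum(stat * e$prob)
  expect_equal(var_approx(y0, pr, mom),
               sum((stat - mu)^2 * e$prob), tolerance = 1e-10)

  # annihilation, scaling, and invariance to covariate shifts
  expect_equal(var_approx(rep(3, n), pr, mom), 0, tolerance = 1e-12)
  expect_equal(var_approx(2 * y0, pr, mom), 4 * var_approx(y0, pr, mom),
               tolerance = 1e-12)
  expect_equal(var_approx(y0 + 5, pr, mom), var_approx(y0, pr, mom),
               tolerance = 1e-10)
})

test_that("var_hat is approximately unbiased for Var(tau_hat) over rerandomizations", {
  n <- 40; tau <- 1
  y0 <- unit_effects(n, "iid", seed = 10)
  proj <- residual_projection(n = n)
  cfgs <- list(
    list(d = permuted_blocks_design(c(1, 1), 4), mc = TRUE),
    list(d = efron_design(), mc = TRUE),
    list(d = urn_design(2, 1, add_e_on_control = 4), mc = TRUE),
    list(d = complete_design(c(1, 1)), mc = FALSE))
  for (cfg in cfgs) {
    mom <- if (cfg$mc)
      assignment_moments(cfg$d, n, method = "monte-carlo", reps = 5e4,
                         seed = 1)
    else assignment_moments(cfg$d, n)
    r <- rerand_stats(cfg$d, n, y0, tau, proj, mom, reps = 4e4, seed = 2)
    expect_lt(abs(mean(r$vh) / var(r$th) - 1), 0.05)
    expect_lt(abs(mean(r$th) - tau), 0.02 * sd(r$th))
  }
})

test_that("vectorized simulation helper agrees with the estimator API", {
  n <- 20; tau <- 0.7
  y0 <- unit_effects(n, "iid", seed = 11)
  proj <- residual_projection(n = n)
  d <- efron_design()
  mom <- assignment_moments(d, n, method = "exact")
  r <- rerand_stats(d, n, y0, tau, proj, mom, reps = 5, seed = 3)
  for (k in 1:5) {
    del <- r$D[, k]; y <- y0 + tau * del
    expect_equal(r$th[k], tau_hat(y, del, proj), tolerance = 1e-10)
    expect_equal(r$vh[k], as.numeric(var_hat(y, del, proj, mom)),
                 tolerance = 1e-10)
  }
})

test_that("randomization and linear-model variance estimates coincide under complete randomization", {
  n <- 200
  y0 <- unit_effects(n, "iid", seed = 12)
  pr <- residual_projection(n = n)
  mom <- assignment_moments(complete_design(c(1, 1)), n)
  set.seed(13)
  for (i in 1:10) {
    del <- rbinom(n, 1, 0.5)
    y <- y0 + del
    expect_lt(abs(as.numeric(var_hat(y, del, pr, mom)) /
                    lm_var_hat(y, del, pr) - 1), 0.05)
  }
})

test_that("conditional variance estimator is exactly conditionally unbiased", {
  n <- 8; tau <- 1.3
  y0 <- unit_effects(n, "iid", seed = 14)
  pr <- residual_projection(n = n)
  d <- efron_design()
  e <- enumerate_sequences(d, n)
  cm <- conditional_moments(d, n, projection = pr)
  a <- ancillary(pr, t(e$delta))
  bins <- round(a / 0.2) * 0.2
  for (b in setdiff(unique(bins), 0)) {
    sel <- bins == b
    w <- e$prob[sel] / sum(e$prob[sel])
    th <- vs <- numeric(sum(sel))
    k <- 0
    for (i in which(sel)) {
      k <- k + 1
      del <- e$delta[i, ]; y <- y0 + tau * del
      th[k] <- tau_hat(y, del, pr)
      vs[k] <- as.numeric(conditional_var_hat(y, del, pr, cm))
    }
    cond_var <- sum(w * th^2) - sum(w * th)^2
    expect_equal(sum(w * th), tau, tolerance = 1e-10)  # conditional mean
    expect_equal(sum(w * vs), cond_var, tolerance = 1e-8)
  }
})

test_that("vacuous conditioning reproduces the unconditional analysis", {
  # blocks of 4 with n = 8: the ancillary statistic is constant, so there
  # is a single bin and conditioning carries no information
  n <- 8
  d <- permuted_blocks_design(c(1, 1), 4)
  pr <- residual_projection(n = n)
  cm <- conditional_moments(d, n, projection = pr)
  expect_length(cm$bins, 1)
  y <- unit_effects(n, "iid", seed = 15) + rep(c(1, 0), 4)
  delta <- assign_sequence(d, n = n, seed = 16)
  mom <- assignment_moments(d, n, method = "exact")
  vc <- as.numeric(conditional_var_hat(y, delta, pr, cm))
  vu <- as.numeric(var_hat(y, delta, pr, mom))
  # the two differ only by the small-sample denominator correction
  M <- pr$M; MV <- M %*% mom$V
  tmv <- sum(M * mom$V); trW <- sum(MV * t(MV))
  expect_equal(vc, vu * tmv^2 / (tmv^2 - trW), tolerance = 1e-10)
  expect_lt(abs(vc / vu - 1), 0.30)
})

test_that("conditional bias: sign and first-order agreement with enumeration", {
  d <- permuted_blocks_design(c(2, 1), 6)
  pr <- residual_projection(n = 10)
  cm <- conditional_moments(d, 10, projection = pr)
  j <- which(cm$bins == 1.6)
  y0 <- 1:10 / 10  # increasing unit effects; late patients are forced to E

  # constant conditional probabilities carry no bias
  expect_equal(conditional_bias(rep(2 / 3, 10), y0, pr, cm$V_c[[j]]), 0,
               tolerance = 1e-10)

  b <- conditional_bias(cm$p_c[, j], y0, pr, cm$V_c[[j]])
  expect_gt(b, 0)

  # exact conditional bias of tau_hat in that bin, by enumeration
  e <- enumerate_sequences(d, 10)
  a <- ancillary(pr, t(e$delta))
  sel <- abs(a - 1.6) < 1e-9
  w <- e$prob[sel] / sum(e$prob[sel])
  th <- apply(e$delta[sel, , drop = FALSE], 1, function(del)
    tau_hat(y0 + 0.5 * del, del, pr))
  exact_bias <- sum(w * th) - 0.5
  expect_gt(exact_bias, 0)
  expect_lt(abs(b / exact_bias - 1), 0.25)
})

test_that("unconditional bias diagnostics for non-constant assignment probabilities", {
  n <- 10
  pr <- residual_projection(n = n)
  d <- biased_coin_design(c(2, 1))
  pv <- marginal_probs(d, n)
  mom <- assignment_moments(d, n, method = "exact")

  # constant probabilities give exactly zero bias
  expect_equal(unconditional_bias(rep(2 / 3, n), 1:n, pr, mom), 0,
               tolerance = 1e-12)

  # unit effects aligned with the probability profile: first-order bias
  # matches the exact enumeration bias closely
  y0 <- 3 * pv
  e <- enum_nondegenerate(enumerate_sequences(d, n), pr)
  th <- apply(e$delta, 1, function(del) tau_hat(y0 + 0.5 * del, del, pr))
  exact_bias <- sum(th * e$prob) - 0.5
  fo <- unconditional_bias(pv, y0, pr, mom)
  expect_lt(abs(fo / exact_bias - 1), 0.10)

  # marginal balance oscillates more and its bias is larger
  dm <- marginal_balance_design(c(2, 1))
  pvm <- marginal_probs(dm, n)
  momm <- assignment_moments(dm, n, method = "exact")
  expect_gt(abs(unconditional_bias(pvm, 3 * pvm, pr, momm)), abs(fo))
})

test_that("augmenting the covariates with the probability profile removes the bias", {
  n <- 10
  pr <- residual_projection(n = n)
  d <- biased_coin_design(c(2, 1))
  pv <- marginal_probs(d, n)
  e <- enum_nondegenerate(enumerate_sequences(d, n), pr)

  bias_under <- function(proj, y0) {
    th <- apply(e$delta, 1, function(del)
      tau_hat(y0 + 0.5 * del, del, proj))
    sum(th * e$prob) - 0.5
  }
  pra <- augment_repair(pr, pv)
  expect_equal(ncol(pra$X), 2)

  # fully aligned unit effects: repair eliminates the bias entirely
  expect_lt(abs(bias_under(pra, 3 * pv)), 1e-10)
  expect_gt(abs(bias_under(pr, 3 * pv)), 0.1)

  # partially aligned unit effects: repair reduces the bias
  y0 <- 3 * pv + 0.2 * seq_len(n)
  expect_lt(abs(bias_under(pra, y0)), abs(bias_under(pr, y0)))

  # a constant profile is collinear with the intercept: warned no-op
  expect_warning(pr2 <- augment_repair(pr, rep(2 / 3, n)), "column space")
  expect_identical(pr2, pr)
})

test_that("z test mechanics", {
  zt <- z_test(1.5, 0.04, tau0 = 1.5)
  expect_equal(zt$z, 0)
  expect_equal(zt$p.value, 1)
  expect_equal(unname(zt$ci), c(1.5 - 1.96 * 0.2, 1.5 + 1.96 * 0.2),
               tolerance = 1e-3)
  expect_error(z_test(1, 0), "positive")
})

test_that("randfit ties the pieces together", {
  set.seed(17)
  n <- 16; tau <- 1.2
  d <- permuted_blocks_design(c(1, 1), 4)
  delta <- assign_sequence(d, n = n, seed = 18)
  df <- data.frame(s = factor(rep(c("a", "b"), each = 8)))
  y0 <- unit_effects(n, "iid", seed = 19)
  df$y <- y0 + tau * delta
  df$delta <- delta

  fit <- randfit(y ~ s, df, design = d, strata = df$s, method = "exact")
  expect_s3_class(fit, "randfit")
  pr <- residual_projection(~ s, data = df)
  expect_equal(unname(coef(fit)), tau_hat(df$y, delta, pr))
  expect_equal(as.numeric(vcov(fit)), as.numeric(fit$var_rand))
  ci <- confint(fit)
  expect_true(ci[1] < coef(fit) && coef(fit) < ci[2])
  expect_false(fit$bias$flag)
  expect_equal(fit$bias$p_vec, rep(0.5, n), tolerance = 1e-12)

  # residuals are orthogonal to the covariates and the assignment
  r <- residuals(fit)
  expect_equal(drop(crossprod(pr$X, r)), c(0, 0), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(sum(delta * r), 0, tolerance = 1e-8)

  # fitted values and variance agree with the least-squares fit on [X, delta]
  lmfit <- lm(y ~ s + delta, df)
  expect_equal(unname(fitted(fit)), unname(fitted(lmfit)),
               tolerance = 1e-10)
  expect_equal(fit$var_lm, unname(vcov(lmfit)["delta", "delta"]),
               tolerance = 1e-10)

  # a design violating constant probability is flagged
  set.seed(20)
  d2 <- marginal_balance_design(c(2, 1))
  delta2 <- assign_sequence(d2, n = n, seed = 21)
  df$delta <- delta2
  df$y <- y0 + tau * delta2
  fit2 <- randfit(y ~ 1, df, design = d2, method = "exact")
  expect_true(fit2$bias$flag)

  # conditional fit attaches a conditional variance
  df$delta <- delta; df$y <- y0 + tau * delta
  fit3 <- randfit(y ~ 1, df, design = d, method = "exact",
                  conditional = TRUE)
  expect_false(is.null(fit3$var_rand_conditional))
  expect_output(print(summary(fit3)), "conditional variance")
})
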