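test_that("allocation fractions and constant assignment rules", {
  expect_equal(alloc_spec(c(1, 1))$p, 0.5)
  expect_equal(alloc_spec(c(2, 1))$p, 2 / 3)
  expect_error(alloc_spec(c(0, 1)))

  expect_equal(marginal_probs(complete_design(c(1, 1)), 5), rep(0.5, 5))
  expect_equal(marginal_probs(complete_design(c(2, 1)), 5), rep(2 / 3, 5))
})

test_that("permuted blocks: conditional probabilities follow the remaining slots", {
  d <- permuted_blocks_design(c(2, 1), 6)
  expect_error(permuted_blocks_design(c(2, 1), 5))

  # empty history: full block, 4 of 6 experimental slots
  expect_equal(d$prob_fn(d$init_state, "1"), 2 / 3)
  # after E,E,E,E within one stratum the experimental slots are exhausted
  st <- d$init_state
  for (i in 1:4) st <- d$advance(st, "1", 1L)[[1]]$state
  expect_equal(d$prob_fn(st, "1"), 0)
  # but a different stratum still sees a full block
  expect_equal(d$prob_fn(st, "2"), 2 / 3)

  # every complete enumeration at n = 10 keeps E(delta_i) = 2/3
  expect_equal(marginal_probs(d, 10), rep(2 / 3, 10), tolerance = 1e-12)
})

test_that("dynamic 2:1 rules match independent history-based oracles exactly", {
  cases <- list(
    list(design = biased_coin_design(c(2, 1)), rule = rule_biased_coin_21),
    list(design = marginal_balance_design(c(2, 1)),
         rule = rule_marginal_balance_21),
    list(design = urn_design(2, 1, add_e_on_control = 2),
         rule = rule_urn_21(2)),
    list(design = urn_design(2, 1, add_e_on_control = 4),
         rule = rule_urn_21(4)),
    list(design = efron_design(), rule = rule_efron()))
  for (cs in cases) {
    expect_equal(marginal_probs(cs$design, 7), oracle_marginals(cs$rule, 7),
                 tolerance = 1e-12)
  }
})

test_that("arm-combining preserves the constant assignment probability", {
  # complete inner randomization collapses to complete 2:1
  d0 <- sequential_combine_design(multiarm_complete_design(3), c(2, 1))
  expect_equal(d0$prob_fn(d0$init_state, "1"), 2 / 3)

  # blocked inner randomization: E(delta_i) = 2/3 for every patient
  d <- sequential_combine_design(multiarm_blocks_design(3, 3), c(2, 1))
  expect_equal(marginal_probs(d, 6), rep(2 / 3, 6), tolerance = 1e-12)
  em <- assignment_moments(d, 6, method = "exact")
  expect_equal(em$mean, rep(2 / 3, 6), tolerance = 1e-12)

  expect_error(sequential_combine_design(multiarm_blocks_design(4, 4),
                                         c(2, 1)))
})

test_that("threshold coin, marginal balance and urns violate constant probability", {
  for (d in list(biased_coin_design(c(2, 1)),
                 marginal_balance_design(c(2, 1)),
                 urn_design(2, 1, add_e_on_control = 2),
                 urn_design(2, 1, add_e_on_control = 4))) {
    pv <- marginal_probs(d, 8)
    expect_gt(max(abs(pv - 2 / 3)), 0.005)
  }
})

test_that("1:1 designs are symmetric under swapping the arm labels", {
  for (d in list(efron_design(), permuted_blocks_design(c(1, 1), 2),
                 complete_design(c(1, 1)))) {
    e <- enumerate_sequences(d, 6)
    key <- apply(e$delta, 1, paste, collapse = "")
    swapped <- apply(1 - e$delta, 1, paste, collapse = "")
    expect_setequal(key, swapped)
    expect_equal(e$prob[match(swapped, key)], e$prob, tolerance = 1e-12)
  }
})

test_that("Pocock-Simon minimization is symmetric and keeps E(delta) = 1/2", {
  ps <- pocock_simon_design(c("site", "sex"))
  frame <- data.frame(site = c("a", "a", "b", "a", "b"),
                      sex = c("m", "f", "m", "m", "f"))
  expect_equal(ps$prob_fn(ps$init_state, as.list(frame[1, ])), 0.5)
  expect_equal(marginal_probs(ps, 5, strata = frame), rep(0.5, 5),
               tolerance = 1e-12)
  # mirrored histories give complemented probabilities
  st1 <- ps$init_state
  st2 <- ps$init_state
  for (i in 1:3) {
    st1 <- ps$advance(st1, as.list(frame[i, ]), 1L)[[1]]$state
    st2 <- ps$advance(st2, as.list(frame[i, ]), 0L)[[1]]$state
  }
  expect_equal(ps$prob_fn(st1, as.list(frame[4, ])),
               1 - ps$prob_fn(st2, as.list(frame[4, ])))
})

test_that("samplers reproduce exact marginal probabilities", {
  reps <- 2e4
  designs <- list(
    biased_coin_design(c(2, 1)),
    marginal_balance_design(c(2, 1)),
    urn_design(2, 1, add_e_on_control = 2),
    permuted_blocks_design(c(2, 1), 6),
    sequential_combine_design(multiarm_blocks_design(3, 3), c(2, 1)))
  for (d in designs) {
    pv <- marginal_probs(d, 8)
    D <- assign_sequence(d, n = 8, reps = reps, seed = 42)
    se <- sqrt(pv * (1 - pv) / reps)
    expect_true(all(abs(rowMeans(D) - pv) < 4 * pmax(se, 1e-6)))
  }
})

test_that("samplers respect block constraints and seeding", {
  d <- permuted_blocks_design(c(2, 1), 6)
  D <- assign_sequence(d, n = 6, reps = 200, seed = 1)
  expect_true(all(colSums(D) == 4))

  D2 <- assign_sequence(d, n = 6, reps = 200, seed = 1)
  expect_identical(D, D2)

  # stratified: block constraint holds within each stratum
  strata <- rep(c("a", "b"), each = 6)
  Ds <- assign_sequence(d, strata = strata, reps = 100, seed = 3)
  expect_true(all(colSums(Ds[1:6, ]) == 4))
  expect_true(all(colSums(Ds[7:12, ]) == 4))

  # generic stepping sampler agrees with the exact marginals too
  ps <- pocock_simon_design("site")
  frame <- data.frame(site = rep("a", 4))
  Dp <- assign_sequence(ps, strata = frame, reps = 4000, seed = 5)
  expect_true(all(abs(rowMeans(Dp) - 0.5) < 4 * sqrt(0.25 / 4000)))
})
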