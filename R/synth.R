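## synthetic trial fixtures and scripted simulation studies

#' Generate unit-effect vectors with controlled temporal structure
#'
#' Builds fixed unit-effect vectors `y0` whose relation to patient entry
#' order is controlled: `"iid"` draws with no structure, `"linear"` a
#' positive trend in entry order, `"low_frequency"` a half-cycle sinusoid
#' over the enrollment window (smooth drift), and `"high_frequency"` an
#' alternating pattern (adjacent patients respond least similarly). For the
#' structured patterns the deterministic component and the (residualized)
#' noise are rescaled so that the regression of `y0` on the pattern attains
#' the requested coefficient of determination `r2` exactly, and the sample
#' variance of `y0` equals `sigma2` exactly.
#'
#' @param n number of patients.
#' @param pattern one of `"iid"`, `"linear"`, `"low_frequency"`,
#'   `"high_frequency"`.
#' @param r2 fraction of the variance of `y0` attributable to the pattern.
#' @param sigma2 sample variance of the generated vector.
#' @param cycles number of sinusoid cycles over the window for
#'   `"low_frequency"` (default 1/2).
#' @param seed optional integer seed.
#' @return Numeric vector of length `n`.
#' @examples
#' y0 <- unit_effects(38, "linear", r2 = 0.5, seed = 1)
#' summary(lm(y0 ~ seq_along(y0)))$r.squared  # exactly 0.5
#' @export
unit_effects <- function(n, pattern = c("iid", "linear", "low_frequency",
                                        "high_frequency"),
                         r2 = 0.5, sigma2 = 1, cycles = 0.5, seed = NULL) {
  pattern <- match.arg(pattern)
  if (r2 < 0 || r2 >= 1) stop("'r2' must be in [0, 1)")
  .with_seed(seed, {
    e <- stats::rnorm(n)
    if (pattern == "iid" || r2 == 0) {
      e <- e - mean(e)
      return(e * sqrt(sigma2 * (n - 1) / sum(e^2)))
    }
    t <- seq_len(n)
    u <- switch(pattern,
      linear = t,
      low_frequency = sin(2 * pi * cycles * (t - 0.5) / n),
      high_frequency = (-1)^t)
    u <- u - mean(u)
    u <- u / sqrt(sum(u^2))
    # residualize the noise on [1, u] so the achieved R^2 is exact
    ee <- e - mean(e); ee <- ee - u * sum(u * ee)
    ee <- ee / sqrt(sum(ee^2))
    ss <- sigma2 * (n - 1)
    sqrt(r2 * ss) * u + sqrt((1 - r2) * ss) * ee
  })
}

#' A 38-patient unequal-allocation trial fixture
#'
#' Constructs the small stratified 2:1 trial used throughout the package's
#' worked analyses: 38 patients categorized by two binary stratification
#' factors with cell counts 10, 8, 11 and 9 for cells (0,0), (0,1), (1,0)
#' and (1,1); entry order drawn at random once (from `seed`) and then held
#' fixed across all rerandomizations; covariate matrix `X` containing an
#' intercept and the two stratum main effects; and two candidate
#' randomization methods, stratified 2:1 permuted blocks of six applied
#' within each cell, and a symmetric three-arm randomization (stratified
#' blocks of three) with two arms combined into the experimental arm.
#'
#' Both designs keep every patient's unconditional assignment probability
#' at 2/3, yet their conditional assignment probabilities given the
#' ancillary statistic diverge from 2/3 for late patients in incomplete
#' blocks -- the fixture exists to exhibit that conditional bias.
#'
#' @param seed integer seed fixing the entry order.
#' @return List with `trial` (data frame: `order`, factors `s1`, `s2`,
#'   `cell`), `formula` (`~ s1 + s2`), `projection`, `strata` (cell labels
#'   for the stratified designs), `design_pbr`, and `design_seq`.
#' @export
make_study_trial <- function(seed = 1) {
  counts <- c(10L, 8L, 11L, 9L)
  lev <- cbind(s1 = c(0, 0, 1, 1), s2 = c(0, 1, 0, 1))
  cell <- rep(1:4, counts)
  ord <- .with_seed(seed, sample.int(38L))
  cell <- cell[ord]
  trial <- data.frame(order = 1:38,
                      s1 = factor(lev[cell, "s1"]),
                      s2 = factor(lev[cell, "s2"]),
                      cell = factor(cell))
  proj <- residual_projection(~ s1 + s2, data = trial)
  list(trial = trial, formula = ~ s1 + s2, projection = proj,
       strata = as.character(trial$cell),
       design_pbr = permuted_blocks_design(c(2, 1), 6),
       design_seq = sequential_combine_design(multiarm_blocks_design(3, 3),
                                              c(2, 1)))
}

#' Scripted simulation studies
#'
#' Runs one of the package's canned studies end to end and returns its
#' results as data frames (optionally written as CSV files to `out_dir`):
#'
#' * `"dynamic_probs"`: exact unconditional assignment probabilities, by
#'   patient, for the four dynamic 2:1 methods (threshold biased coin,
#'   marginal balance, naive urn, corrected urn), with their limits.
#' * `"conditional_bias"`: for the [make_study_trial()] fixture, per-bin
#'   conditional assignment probabilities and the normalized conditional
#'   bias of the estimator under a linear unit-effect trend.
#' * `"variance_compare"`: mean randomization and linear-model variance
#'   estimates over rerandomizations under iid, low-frequency and
#'   high-frequency unit effects.
#' * `"coverage"`: empirical size and CI coverage of the normal
#'   approximation under complete randomization.
#'
#' @param name study name (see above).
#' @param reps Monte Carlo replicates where applicable.
#' @param n patients for the `"variance_compare"` and `"coverage"` studies.
#' @param r2 trend strength for structured unit effects.
#' @param seed integer seed.
#' @param out_dir optional directory for CSV output.
#' @return A data frame (or named list of data frames), invisibly when
#'   `out_dir` is given.
#' @export
run_study <- function(name = c("dynamic_probs", "conditional_bias",
                               "variance_compare", "coverage"),
                      reps = 2e4, n = 50, r2 = 0.5, seed = 1,
                      out_dir = NULL) {
  name <- match.arg(name)
  out <- switch(name,
    dynamic_probs = {
      designs <- list(
        biased_coin = biased_coin_design(c(2, 1)),
        marginal_balance = marginal_balance_design(c(2, 1)),
        urn_naive = urn_design(2, 1, add_e_on_control = 2),
        urn_corrected = urn_design(2, 1, add_e_on_control = 4))
      tab <- data.frame(patient = 1:20)
      for (nm in names(designs))
        tab[[nm]] <- round(marginal_probs(designs[[nm]], 20), 3)
      urns <- designs[c("urn_naive", "urn_corrected")]
      limits <- vapply(urns, function(d)
        round(as.numeric(limiting_prob(d)), 3), numeric(1))
      list(probabilities = tab,
           limits = data.frame(method = names(limits), limit = limits))
    },
    conditional_bias = {
      fx <- make_study_trial(seed)
      y0 <- unit_effects(38, "linear", r2 = r2, seed = seed + 1)
      res <- lapply(list(pbr = fx$design_pbr, sequential = fx$design_seq),
        function(d) {
          cm <- conditional_moments(d, 38, fx$strata, fx$projection,
                                    method = "monte-carlo", reps = reps,
                                    seed = seed)
          data.frame(bin = cm$bins, mass = cm$mass,
                     normalized_bias = vapply(seq_along(cm$bins), function(j)
                       conditional_bias(cm$p_c[, j], y0, fx$projection,
                                        cm$V_c[[j]], normalized = TRUE),
                       numeric(1)))
        })
      res
    },
    variance_compare = {
      designs <- list(efron = efron_design(),
                      pbr = permuted_blocks_design(c(1, 1), 4))
      patterns <- c("iid", "low_frequency", "high_frequency")
      rows <- list()
      for (dn in names(designs)) {
        d <- designs[[dn]]
        mom <- assignment_moments(d, n, method = "monte-carlo", reps = reps,
                                  seed = seed)
        proj <- residual_projection(n = n)
        for (pat in patterns) {
          y0 <- unit_effects(n, pat, r2 = if (pat == "iid") 0 else r2,
                             seed = seed + 2)
          rows[[length(rows) + 1]] <- data.frame(
            design = dn, pattern = pat,
            var_rand = var_approx(y0, proj, mom),
            var_lm_expect = lm_var_expectation(y0, proj, mom))
        }
      }
      do.call(rbind, rows)
    },
    coverage = {
      d <- complete_design(c(1, 1))
      proj <- residual_projection(n = n)
      mom <- assignment_moments(d, n)
      y0 <- unit_effects(n, "iid", seed = seed)
      D <- assign_sequence(d, n = n, reps = reps, seed = seed + 1)
      a <- ancillary(proj, D)
      covered <- logical(reps); rejected <- logical(reps)
      My0 <- drop(proj$M %*% y0)
      for (r in seq_len(reps)) {
        th <- sum(D[, r] * My0) / a[r]
        v <- as.numeric(var_hat(y0, D[, r], proj, mom))
        zt <- z_test(th, v)
        covered[r] <- zt$ci["lower"] <= 0 && 0 <= zt$ci["upper"]
        rejected[r] <- zt$p.value < 0.05
      }
      data.frame(n = n, reps = reps, coverage = mean(covered),
                 size = mean(rejected))
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tabs <- if (is.data.frame(out)) stats::setNames(list(out), name) else out
    for (nm in names(tabs))
      utils::write.csv(tabs[[nm]],
                       file.path(out_dir, paste0(name, "_", nm, ".csv")),
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
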