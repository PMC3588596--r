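## exact engine: forward dynamic programming over a design's state
## abstraction, and full enumeration of assignment sequences for small n

## one forward step: from a state distribution (list of list(state, w)),
## return list(prob = P(delta_i = 1), dist = distribution after patient i)
.dp_step <- function(design, dist, stratum, state_cap) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  pi1 <- 0
  for (node in dist) {
    p <- design$prob_fn(node$state, stratum)
    pi1 <- pi1 + node$w * p
    for (d in c(1L, 0L)) {
      wd <- node$w * (if (d == 1L) p else 1 - p)
      if (wd <= 0) next
      for (nx in design$advance(node$state, stratum, d)) {
        w2 <- wd * nx$w
        if (w2 <= 0) next
        key <- design$state_key(nx$state)
        cur <- env[[key]]
        if (is.null(cur)) env[[key]] <- list(state = nx$state, w = w2)
        else env[[key]]$w <- cur$w + w2
      }
    }
  }
  out <- as.list(env, all.names = TRUE)
  if (length(out) > state_cap)
    stop("state space exceeded 'state_cap' (", state_cap,
         "); use Monte Carlo moments instead")
  mass <- sum(vapply(out, `[[`, numeric(1), "w"))
  if (abs(mass - 1) > 1e-9) stop("state-distribution mass drifted: ", mass)
  list(prob = pi1, dist = unname(out))
}

#' Exact unconditional assignment probabilities
#'
#' Computes `P(delta_i = 1)` for patients `i = 1..n` by exact forward
#' dynamic programming over the design's state abstraction: the state
#' distribution is propagated patient by patient, merging equivalent states,
#' so the cost is linear in `n` times the number of reachable states.
#'
#' A design satisfies the constant-probability requirement when this vector
#' is constant at the allocation fraction `p`; threshold biased coins,
#' marginal-balance minimization and the naive 2:1 urn generalization
#' visibly fail it.
#'
#' @inheritParams assign_sequence
#' @param state_cap maximum number of simultaneously tracked states.
#' @return Numeric vector of length `n`.
#' @examples
#' round(marginal_probs(biased_coin_design(c(2, 1)), 5), 3)
#' # 0.667 0.744 0.467 0.674 0.761
#' @export
marginal_probs <- function(design, n, strata = NULL, state_cap = 1e5) {
  sl <- .norm_strata(strata, n)
  dist <- list(list(state = design$init_state, w = 1))
  out <- numeric(n)
  for (i in seq_len(n)) {
    step <- .dp_step(design, dist, sl[[i]], state_cap)
    out[i] <- step$prob
    dist <- step$dist
  }
  out
}

#' Limiting assignment probability of an unstratified design
#'
#' Runs the exact forward recursion of [marginal_probs()] until successive
#' unconditional assignment probabilities change by less than `tol` (or
#' `horizon` patients have been processed) and reports the terminal value.
#'
#' @inheritParams marginal_probs
#' @param horizon maximum patient index examined.
#' @param tol convergence tolerance on successive probabilities.
#' @return The terminal probability, with attributes `converged` (logical)
#'   and `iterations`. A warning is issued if the sequence has not settled
#'   within the horizon.
#' @examples
#' round(limiting_prob(urn_design(2, 1, add_e_on_control = 2)), 3)  # 0.586
#' @export
limiting_prob <- function(design, horizon = 500, tol = 1e-6,
                          state_cap = 1e6) {
  if (design$stratified)
    stop("limiting_prob() requires a stratification-free design")
  dist <- list(list(state = design$init_state, w = 1))
  prev <- NA_real_; val <- NA_real_; conv <- FALSE; i <- 0
  while (i < horizon) {
    i <- i + 1
    step <- .dp_step(design, dist, "1", state_cap)
    val <- step$prob
    dist <- step$dist
    if (!is.na(prev) && abs(val - prev) < tol) { conv <- TRUE; break }
    prev <- val
  }
  if (!conv)
    warning("assignment probabilities not settled within the horizon; ",
            "reporting the last value")
  structure(val, converged = conv, iterations = i)
}

#' Enumerate all assignment sequences of a design
#'
#' Produces every assignment sequence with positive probability for a small
#' trial, with its exact probability, by depth-first traversal of the
#' assignment tree (zero-probability branches are pruned; stochastic inner
#' transitions are marginalized via the state distribution carried along
#' each path). Supports exact moments and any functional of the assignment
#' distribution.
#'
#' @inheritParams marginal_probs
#' @param max_sequences guard on the number of enumerated sequences.
#' @return A list with `delta` (matrix, one row per sequence) and `prob`
#'   (numeric, summing to 1).
#' @examples
#' e <- enumerate_sequences(permuted_blocks_design(c(2, 1), 6), 6)
#' nrow(e$delta)  # choose(6, 4) = 15 equiprobable sequences
#' @export
enumerate_sequences <- function(design, n, strata = NULL,
                                max_sequences = 2^20) {
  if (n > 24) stop("enumeration is limited to n <= 24")
  sl <- .norm_strata(strata, n)
  res_d <- vector("list", 1024); res_p <- numeric(1024); cnt <- 0L

  push <- function(delta, pr) {
    cnt <<- cnt + 1L
    if (cnt > max_sequences) stop("more than 'max_sequences' sequences")
    if (cnt > length(res_p)) {
      length(res_d) <<- 2L * length(res_d)
      length(res_p) <<- 2L * length(res_p)
    }
    res_d[[cnt]] <<- delta; res_p[cnt] <<- pr
  }
  branch_dist <- function(dist, stratum, d) {
    # condition the state distribution on assignment d
    env <- new.env(hash = TRUE, parent = emptyenv())
    tot <- 0
    for (node in dist) {
      p <- design$prob_fn(node$state, stratum)
      wd <- node$w * (if (d == 1L) p else 1 - p)
      if (wd <= 0) next
      tot <- tot + wd
      for (nx in design$advance(node$state, stratum, d)) {
        w2 <- wd * nx$w
        if (w2 <= 0) next
        key <- design$state_key(nx$state)
        cur <- env[[key]]
        if (is.null(cur)) env[[key]] <- list(state = nx$state, w = w2)
        else env[[key]]$w <- cur$w + w2
      }
    }
    if (tot <= 0) return(NULL)
    out <- unname(as.list(env, all.names = TRUE))
    for (j in seq_along(out)) out[[j]]$w <- out[[j]]$w / tot
    list(dist = out, p = tot)
  }
  rec <- function(i, delta, dist, pr) {
    if (i > n) { push(delta, pr); return(invisible()) }
    for (d in c(1L, 0L)) {
      br <- branch_dist(dist, sl[[i]], d)
      if (is.null(br)) next
      rec(i + 1L, c(delta, d), br$dist, pr * br$p)
    }
  }
  rec(1L, integer(0), list(list(state = design$init_state, w = 1)), 1)
  delta <- do.call(rbind, res_d[seq_len(cnt)])
  prob <- res_p[seq_len(cnt)]
  stopifnot(abs(sum(prob) - 1) < 1e-9)
  list(delta = delta, prob = prob)
}

#' Moments of the assignment vector
#'
#' Computes the mean vector `E(delta)` and variance-covariance matrix
#' `V = Var(delta)` of the assignment indicators, either exactly (by full
#' enumeration, feasible for small `n`) or by Monte Carlo rerandomization
#' (the sample mean and covariance over `reps` replicate assignments).
#'
#' @inheritParams assign_sequence
#' @param method `"exact"` (enumeration), `"monte-carlo"`, or `"auto"`
#'   (exact up to `n = 14` for deterministic-state designs, Monte Carlo
#'   otherwise). Complete randomization always uses its closed form
#'   `V = p(1-p) I`.
#' @param reps Monte Carlo replicates.
#' @return An object of class `"assignment_moments"`: list with `mean`, `V`,
#'   `source` (`"exact"` or `"monte_carlo"`), `reps` and `n`.
#' @examples
#' m <- assignment_moments(permuted_blocks_design(c(1, 1), 2), n = 4)
#' m$V  # -0.25 within block pairs, 0 across blocks
#' @export
assignment_moments <- function(design, n, strata = NULL,
                               method = c("auto", "exact", "monte-carlo"),
                               reps = 1e5, seed = NULL) {
  method <- match.arg(method)
  is_complete <- identical(substr(design$name, 1, 8), "complete") ||
    identical(design$params$inner$kind, "complete")
  if (is_complete && method != "monte-carlo") {
    p <- design$alloc$p
    return(structure(list(mean = rep(p, n), V = diag(p * (1 - p), n),
                          source = "exact", reps = NA_integer_, n = n),
                     class = "assignment_moments"))
  }
  if (method == "auto") method <- if (n <= 14) "exact" else "monte-carlo"
  if (method == "exact") {
    e <- enumerate_sequences(design, n, strata)
    mu <- colSums(e$delta * e$prob)
    Exx <- crossprod(e$delta, e$delta * e$prob)
    V <- Exx - tcrossprod(mu)
    structure(list(mean = mu, V = (V + t(V)) / 2, source = "exact",
                   reps = NA_integer_, n = n),
              class = "assignment_moments")
  } else {
    sl <- .norm_strata(strata, n)
    D <- .with_seed(seed, rand_draws(design, sl, as.integer(reps)))
    structure(list(mean = rowMeans(D), V = stats::cov(t(D)),
                   source = "monte_carlo", reps = as.integer(reps), n = n),
              class = "assignment_moments")
  }
}

#' @export
print.assignment_moments <- function(x, ...) {
  cat(sprintf("Assignment moments (%s%s), n = %d\n", x$source,
              if (x$source == "monte_carlo") sprintf(", %d reps", x$reps)
              else "", x$n))
  cat("  E(delta):", paste(format(round(x$mean, 3)), collapse = " "), "\n")
  invisible(x)
}

## nearest-multiple binning of the ancillary statistic (round half to even,
## matching the grouping of reported conditional summaries)
.bin_values <- function(a, bin_width) round(a / bin_width) * bin_width

#' Conditional assignment moments given the ancillary statistic
#'
#' Groups assignment sequences by the value of the ancillary quadratic form
#' `delta' M delta` (rounded to the nearest `bin_width`) and computes, per
#' bin, its probability mass, the conditional mean vector
#' `p_c = E(delta | bin)` and the conditional variance matrix `V_c`. Exact
#' mode enumerates all sequences; Monte Carlo mode accumulates over
#' rerandomizations.
#'
#' For symmetric 1:1 designs every `p_c` is constant at 1/2, but with
#' unequal allocation the conditional assignment probabilities of late
#' patients (incomplete blocks) diverge from the allocation fraction, which
#' is what makes conditional inference delicate in small unbalanced trials.
#'
#' @inheritParams assignment_moments
#' @param projection a [`projection`][residual_projection] for the covariate
#'   matrix defining the ancillary statistic.
#' @param bin_width grouping resolution for the ancillary values.
#' @return An object of class `"conditional_moments"`: list with `bins`
#'   (bin centers), `mass`, `p_c` (n x bins matrix), `V_c` (list of
#'   matrices), `bin_width`, `source`, `n`.
#' @examples
#' d <- permuted_blocks_design(c(2, 1), 6)
#' pr <- residual_projection(n = 10)
#' cm <- conditional_moments(d, 10, projection = pr)
#' cm$p_c[, cm$bins == 1.6]  # 2/3 for patients 1-6, then 1
#' @export
conditional_moments <- function(design, n, strata = NULL, projection,
                                bin_width = 0.2,
                                method = c("exact", "monte-carlo"),
                                reps = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (method == "exact") {
    e <- enumerate_sequences(design, n, strata)
    D <- e$delta; w <- e$prob
  } else {
    sl <- .norm_strata(strata, n)
    D <- t(.with_seed(seed, rand_draws(design, sl, as.integer(reps))))
    w <- rep(1 / nrow(D), nrow(D))
  }
  a <- ancillary(projection, t(D))
  bin <- .bin_values(a, bin_width)
  ub <- sort(unique(bin))
  mass <- numeric(length(ub))
  p_c <- matrix(NA_real_, n, length(ub))
  V_c <- vector("list", length(ub))
  for (j in seq_along(ub)) {
    sel <- bin == ub[j]
    wj <- w[sel]; mass[j] <- sum(wj); wj <- wj / mass[j]
    Dj <- D[sel, , drop = FALSE]
    mu <- colSums(Dj * wj)
    Exx <- crossprod(Dj, Dj * wj)
    V <- Exx - tcrossprod(mu)
    p_c[, j] <- mu
    V_c[[j]] <- (V + t(V)) / 2
  }
  structure(list(bins = ub, mass = mass, p_c = p_c, V_c = V_c,
                 bin_width = bin_width, source = method, n = n,
                 reps = if (method == "exact") NA_integer_
                        else as.integer(reps)),
            class = "conditional_moments")
}

#' @export
print.conditional_moments <- function(x, ...) {
  cat(sprintf(
    "Conditional assignment moments (%s), n = %d, bin width %.3g\n",
    x$source, x$n, x$bin_width))
  print(data.frame(bin = x$bins, mass = round(x$mass, 4)), row.names = FALSE)
  invisible(x)
}

#' @describeIn conditional_moments Plot the per-bin conditional assignment
#'   probabilities `p_c` against patient order (one line per bin).
#' @param x a `"conditional_moments"` object.
#' @param ... further arguments passed to [graphics::matplot()].
#' @export
plot.conditional_moments <- function(x, ...) {
  graphics::matplot(seq_len(x$n), x$p_c, type = "l", lty = 1,
                    xlab = "patient order",
                    ylab = "conditional P(experimental)", ...)
  graphics::abline(h = 0.5, col = "grey", lty = 3)
  graphics::legend("bottomleft", legend = format(x$bins),
                   col = seq_along(x$bins), lty = 1, cex = 0.7,
                   title = "ancillary bin")
  invisible(x)
}
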