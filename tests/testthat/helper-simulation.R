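# Vectorized rerandomization summaries under unit-treatment additivity
# (y_r = y0 + tau * delta_r): replicate estimates, variance estimates and
# null-distribution variances, for property-style simulation tests.
rerand_stats <- function(design, n, y0, tau, proj, mom, reps, seed,
                         strata = NULL) {
  D <- assign_sequence(design, n = n, strata = strata, reps = reps,
                       seed = seed)
  M <- proj$M; V <- mom$V
  A <- M %*% D
  a <- colSums(D * A)
  ok <- a > 1e-9
  U <- drop(M %*% y0) + tau * A          # column r holds M y_r
  th <- colSums(D * U)[ok] / a[ok]
  tmv <- sum(M * V); MV <- M %*% V; trW <- sum(MV * t(MV))
  Q <- colSums(U * (V %*% U))[ok]
  vh <- pmax((Q - th^2 * trW) / tmv^2, 0)
  list(th = th, vh = vh, null_var = Q / tmv^2, a = a[ok],
       tmv = tmv, trW = trW, D = D[, ok, drop = FALSE], n_ok = sum(ok))
}

# exact expectation of f(delta) over an enumeration, conditioned on
# non-degenerate assignments (delta' M delta > 0)
enum_nondegenerate <- function(enum, proj) {
  a <- ancillary(proj, t(enum$delta))
  ok <- a > 1e-9
  list(delta = enum$delta[ok, , drop = FALSE],
       prob = enum$prob[ok] / sum(enum$prob[ok]), a = a[ok])
}
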