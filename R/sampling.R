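## strata handling --------------------------------------------------------
##
## Engines accept `strata` as NULL (one stratum), an atomic vector/factor of
## labels, or a data frame (one row per patient; required for Pocock-Simon).
## Internally each patient's stratum is one element of a list.
.norm_strata <- function(strata, n) {
  if (is.null(strata)) return(rep(list("1"), n))
  if (is.data.frame(strata)) {
    if (nrow(strata) != n) stop("'strata' has the wrong number of rows")
    return(lapply(seq_len(n), function(i) as.list(strata[i, , drop = FALSE])))
  }
  if (length(strata) != n) stop("'strata' has the wrong length")
  as.list(as.character(strata))
}

## restore-on-exit seeding; seed = NULL uses the session RNG stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## replicate draws --------------------------------------------------------

## rand_draws(design, strata_list, reps): integer matrix n x reps of
## assignment indicators, using the current RNG stream. Dispatches to
## vectorized samplers where the design structure allows.
rand_draws <- function(design, strata, reps) UseMethod("rand_draws")

#' @export
rand_draws.count_design <- function(design, strata, reps) {
  n <- length(strata)
  out <- matrix(0L, n, reps)
  ne <- integer(reps); nc <- integer(reps)
  rule <- design$count_rule
  for (i in seq_len(n)) {
    p <- rule(ne, nc)
    d <- as.integer(stats::runif(reps) < p)
    out[i, ] <- d
    ne <- ne + d; nc <- nc + 1L - d
  }
  out
}

## vectorized within-stratum block permutations: for each (replicate, block)
## draw a random permutation of the block template by ranking uniform keys
.block_perm_draws <- function(template, nblocks, reps) {
  b <- length(template)
  ncol <- nblocks * reps
  key <- stats::runif(b * ncol)
  ord <- order(rep(seq_len(ncol), each = b), key)
  rk <- integer(b * ncol)
  rk[ord] <- rep(seq_len(b), ncol)
  matrix(template[rk], nrow = b * nblocks)  # (b*nblocks) x reps
}

#' @export
rand_draws.pbr_design <- function(design, strata, reps) {
  n <- length(strata)
  lab <- vapply(strata, function(s) as.character(s)[1], character(1))
  bs <- design$params$block_size
  eb <- bs %/% (design$alloc$r1 + design$alloc$r2) * design$alloc$r1
  template <- rep(c(1L, 0L), c(eb, bs - eb))
  out <- matrix(0L, n, reps)
  for (s in unique(lab)) {
    idx <- which(lab == s)
    nb <- ceiling(length(idx) / bs)
    draws <- .block_perm_draws(template, nb, reps)
    out[idx, ] <- draws[seq_along(idx), ]
  }
  out
}

#' @export
rand_draws.seq_combine_design <- function(design, strata, reps) {
  inner <- design$params$inner
  r1 <- design$alloc$r1
  n <- length(strata)
  if (identical(inner$kind, "complete")) {
    return(matrix(as.integer(stats::runif(n * reps) < design$alloc$p),
                  n, reps))
  }
  if (identical(inner$kind, "blocks")) {
    lab <- vapply(strata, function(s) as.character(s)[1], character(1))
    bs <- inner$block_size
    per <- bs %/% inner$arms
    template <- rep(seq_len(inner$arms), each = per)
    out <- matrix(0L, n, reps)
    for (s in unique(lab)) {
      idx <- which(lab == s)
      nb <- ceiling(length(idx) / bs)
      arms <- .block_perm_draws(template, nb, reps)
      out[idx, ] <- (arms[seq_along(idx), , drop = FALSE] <= r1) + 0L
    }
    return(out)
  }
  NextMethod()
}

## generic fallback: step through the rule patient by patient
#' @export
rand_draws.rand_design <- function(design, strata, reps) {
  n <- length(strata)
  out <- matrix(0L, n, reps)
  for (r in seq_len(reps)) {
    st <- design$init_state
    for (i in seq_len(n)) {
      p <- design$prob_fn(st, strata[[i]])
      d <- as.integer(stats::runif(1) < p)
      out[i, r] <- d
      nxt <- design$advance(st, strata[[i]], d)
      if (length(nxt) == 1L) st <- nxt[[1]]$state
      else {
        w <- vapply(nxt, `[[`, numeric(1), "w")
        st <- nxt[[sample.int(length(nxt), 1L, prob = w)]]$state
      }
    }
  }
  out
}

#' Sample treatment-assignment sequences from a design
#'
#' Draws `reps` complete assignment sequences for `n` patients (in their
#' fixed entry order) by applying the design's sequential rule. Replicates
#' are independent; the draw is reproducible given `seed`.
#'
#' @param design a [`rand_design`][complete_design] object.
#' @param n number of patients; defaults to the length of `strata`.
#' @param strata per-patient stratum labels (vector), or a data frame of
#'   stratification factors, or `NULL` for an unstratified trial.
#' @param reps number of replicate sequences.
#' @param seed optional integer seed (the session RNG state is restored).
#' @return An integer matrix with `n` rows and `reps` columns (a plain
#'   integer vector if `reps = 1`); entry 1 denotes an experimental
#'   assignment.
#' @examples
#' d <- permuted_blocks_design(c(2, 1), 6)
#' assign_sequence(d, n = 6, seed = 1)  # always 4 experimental per block
#' @export
assign_sequence <- function(design, n = NULL, strata = NULL, reps = 1,
                            seed = NULL) {
  if (is.null(n)) {
    if (is.null(strata)) stop("give 'n' or 'strata'")
    n <- if (is.data.frame(strata)) nrow(strata) else length(strata)
  }
  sl <- .norm_strata(strata, n)
  out <- .with_seed(seed, rand_draws(design, sl, as.integer(reps)))
  if (reps == 1) drop(out) else out
}
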