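#' Allocation specification
#'
#' Describes the planned allocation ratio `r1:r2` of experimental to control
#' patients. The allocation fraction `p = r1 / (r1 + r2)` is the target
#' unconditional probability that a patient is assigned to the experimental
#' arm: 1:1 allocation gives `p = 1/2`, 2:1 allocation gives `p = 2/3`.
#'
#' @param ratio integer vector of length 2, `c(r1, r2)`, both positive.
#' @return An object of class `"alloc_spec"`: list with components `r1`, `r2`
#'   and `p`.
#' @examples
#' alloc_spec(c(2, 1))$p  # 2/3
#' @export
alloc_spec <- function(ratio = c(1, 1)) {
  if (length(ratio) != 2 || any(ratio < 1) || any(ratio != round(ratio)))
    stop("'ratio' must be two positive integers c(r1, r2)")
  r1 <- as.integer(ratio[1]); r2 <- as.integer(ratio[2])
  structure(list(r1 = r1, r2 = r2, p = r1 / (r1 + r2)), class = "alloc_spec")
}

#' @export
print.alloc_spec <- function(x, ...) {
  cat(sprintf("allocation %d:%d (p = %.4g)\n", x$r1, x$r2, x$p))
  invisible(x)
}

## Internal constructor for sequential randomization designs.
##
## A design is a sequential assignment rule exposed through three functions:
##   prob_fn(state, stratum)        P(delta_i = 1 | state, stratum)
##   advance(state, stratum, delta) distribution over successor states, as a
##                                  list of list(state =, w =) with weights
##                                  summing to 1 (stochastic transitions arise
##                                  for arm-combining designs, where the binary
##                                  assignment does not determine the inner arm)
##   state_key(state)               a character key identifying the state, so
##                                  that the exact engine can merge equivalent
##                                  states in its forward pass
new_rand_design <- function(name, alloc, params, init_state, prob_fn, advance,
                            state_key, subclass = NULL, count_rule = NULL,
                            stratified = FALSE) {
  structure(
    list(name = name, alloc = alloc, params = params, init_state = init_state,
         prob_fn = prob_fn, advance = advance, state_key = state_key,
         count_rule = count_rule, stratified = stratified),
    class = c(subclass, "rand_design"))
}

#' @export
print.rand_design <- function(x, ...) {
  cat(sprintf("Randomization design: %s\n", x$name))
  cat(sprintf("  allocation %d:%d (p = %.4g)\n",
              x$alloc$r1, x$alloc$r2, x$alloc$p))
  if (length(x$params)) {
    pp <- vapply(x$params, function(v)
      if (is.function(v)) "<function>" else paste(format(v), collapse = ","),
      character(1))
    cat("  parameters:", paste(names(pp), pp, sep = " = ", collapse = "; "),
        "\n")
  }
  invisible(x)
}

## deterministic transition helper
.det <- function(state) list(list(state = state, w = 1))

## designs whose state is the pair of previous arm counts (n_e, n_c) share
## this machinery; `rule(ne, nc)` must be vectorized over its arguments
.count_design <- function(name, alloc, params, rule) {
  new_rand_design(
    name, alloc, params,
    init_state = c(ne = 0L, nc = 0L),
    prob_fn = function(state, stratum) rule(state[[1]], state[[2]]),
    advance = function(state, stratum, delta)
      .det(c(ne = state[[1]] + delta, nc = state[[2]] + 1L - delta)),
    state_key = function(state) paste0(state[[1]], ",", state[[2]]),
    subclass = "count_design",
    count_rule = rule)
}

#' Complete randomization
#'
#' Assigns every patient to the experimental arm independently with the
#' allocation fraction `p = r1/(r1+r2)`, regardless of history. Under this
#' design the assignment vector has `Var(delta) = p(1-p) I`.
#'
#' @inheritParams alloc_spec
#' @return A `"rand_design"` object.
#' @examples
#' d <- complete_design(c(2, 1))
#' marginal_probs(d, 4)  # 2/3 throughout
#' @export
complete_design <- function(ratio = c(1, 1)) {
  al <- alloc_spec(ratio)
  .count_design(sprintf("complete randomization %d:%d", al$r1, al$r2),
                al, list(), rule = function(ne, nc) rep(al$p, length(ne)))
}

#' Permuted-blocks randomization
#'
#' Assignments are drawn without replacement from fixed-composition blocks of
#' `block_size` patients containing `block_size * r1/(r1+r2)` experimental
#' slots, applied independently within each stratum. A new block starts when
#' the previous one is exhausted; a final incomplete block is simply truncated
#' at the end of enrollment. The conditional assignment probability is the
#' fraction of experimental slots remaining in the current block.
#'
#' @inheritParams alloc_spec
#' @param block_size block length; must be a multiple of `r1 + r2`.
#' @return A `"rand_design"` object. Pass a stratum label vector to the
#'   engines/samplers to block within strata.
#' @examples
#' d <- permuted_blocks_design(c(2, 1), 6)
#' marginal_probs(d, 10)  # 2/3 for every patient
#' @export
permuted_blocks_design <- function(ratio = c(1, 1), block_size) {
  al <- alloc_spec(ratio)
  k <- al$r1 + al$r2
  if (length(block_size) != 1 || block_size < k || block_size %% k != 0)
    stop("'block_size' must be a positive multiple of r1 + r2")
  block_size <- as.integer(block_size)
  eb <- block_size %/% k * al$r1  # experimental slots per block

  current <- function(state, s) {
    st <- state[[s]]
    if (is.null(st) || st[2] == 0L) c(eb, block_size) else st
  }
  new_rand_design(
    sprintf("permuted blocks %d:%d, block size %d", al$r1, al$r2, block_size),
    al, list(block_size = block_size),
    init_state = list(),
    prob_fn = function(state, stratum) {
      st <- current(state, as.character(stratum))
      st[1] / st[2]
    },
    advance = function(state, stratum, delta) {
      s <- as.character(stratum)
      st <- current(state, s)
      st <- c(st[1] - delta, st[2] - 1L)
      if (st[2] == 0L) state[[s]] <- NULL else state[[s]] <- st
      .det(state)
    },
    state_key = function(state) {
      if (!length(state)) return(".")
      nm <- sort(names(state))
      paste(nm, vapply(state[nm], paste, character(1), collapse = "/"),
            sep = ":", collapse = ";")
    },
    subclass = "pbr_design", stratified = TRUE)
}

#' Threshold biased-coin randomization
#'
#' Generalizes Efron's biased coin to an `r1:r2` allocation target. With
#' `n_e` and `n_c` the numbers of patients previously assigned to the
#' experimental and control arms, the imbalance is `d = n_e/r1 - n_c/r2`.
#' When `d <= -threshold` (experimental under-represented) the next patient
#' is assigned to the experimental arm with probability `p_under`; when
#' `d >= threshold`, with probability `p_over`; otherwise with the allocation
#' fraction `p`. The first patient is always assigned with probability `p`.
#'
#' For 2:1 allocation with the defaults (`p_under = 0.9`, `p_over = 0.2`,
#' `threshold = 1`) this is the natural 2:1 biased coin whose unconditional
#' assignment probabilities oscillate instead of staying at 2/3 -- see
#' [marginal_probs()].
#'
#' @inheritParams alloc_spec
#' @param p_under probability of an experimental assignment when the
#'   experimental arm is under-represented beyond the threshold.
#' @param p_over probability of an experimental assignment when the
#'   experimental arm is over-represented beyond the threshold.
#' @param threshold nonnegative trigger on `|n_e/r1 - n_c/r2|`; the biased
#'   coin is used when the imbalance reaches the threshold (inclusive).
#' @return A `"rand_design"` object.
#' @examples
#' round(marginal_probs(biased_coin_design(c(2, 1)), 5), 3)
#' @export
biased_coin_design <- function(ratio = c(2, 1), p_under = 0.9, p_over = 0.2,
                               threshold = 1) {
  al <- alloc_spec(ratio)
  if (!(p_over < al$p && al$p < p_under && p_over > 0 && p_under < 1))
    stop("need 0 < p_over < p < p_under < 1")
  .count_design(
    sprintf("biased coin %d:%d (threshold %g)", al$r1, al$r2, threshold),
    al, list(p_under = p_under, p_over = p_over, threshold = threshold),
    rule = function(ne, nc) {
      d <- ne / al$r1 - nc / al$r2
      ifelse(d <= -threshold, p_under, ifelse(d >= threshold, p_over, al$p))
    })
}

#' Efron's biased coin (1:1)
#'
#' Classic biased-coin randomization for balanced allocation: the
#' under-represented arm is favored with probability `bias` whenever the arm
#' counts differ; ties are broken with a fair coin. A special case of
#' [biased_coin_design()].
#'
#' @param bias probability with which the under-represented arm is assigned,
#'   in (1/2, 1).
#' @return A `"rand_design"` object.
#' @export
efron_design <- function(bias = 2/3) {
  d <- biased_coin_design(c(1, 1), p_under = bias, p_over = 1 - bias,
                          threshold = 1)
  d$name <- sprintf("Efron biased coin (bias %.3g)", bias)
  d
}

#' Marginal-balance minimization for unequal allocation
#'
#' Dynamic randomization that compares the imbalance that *would result* from
#' each possible assignment of the current patient, using the allocation-
#' normalized metric `|n_e/r1 - n_c/r2|`. If assigning the experimental arm
#' yields the smaller post-assignment imbalance, the experimental arm is
#' assigned with probability `p_under`; if the control assignment yields the
#' smaller value, with probability `p_over`; ties (including the first
#' patient) use the allocation fraction `p`.
#'
#' With 2:1 allocation this rule's unconditional assignment probabilities
#' depart severely from 2/3 (e.g. for patients 2-5 they are 0.433, 0.807,
#' 0.881, 0.342), making it unsuitable for randomization-model estimation.
#'
#' @inheritParams biased_coin_design
#' @return A `"rand_design"` object.
#' @examples
#' round(marginal_probs(marginal_balance_design(c(2, 1)), 5), 3)
#' @export
marginal_balance_design <- function(ratio = c(2, 1), p_under = 0.9,
                                    p_over = 0.2) {
  al <- alloc_spec(ratio)
  if (!(p_over < al$p && al$p < p_under && p_over > 0 && p_under < 1))
    stop("need 0 < p_over < p < p_under < 1")
  metric <- function(ne, nc) abs(ne / al$r1 - nc / al$r2)
  .count_design(
    sprintf("marginal balance %d:%d", al$r1, al$r2),
    al, list(p_under = p_under, p_over = p_over),
    rule = function(ne, nc) {
      ve <- metric(ne + 1L, nc); vc <- metric(ne, nc + 1L)
      # first patient and ties use the allocation fraction
      ifelse(ne + nc == 0L, al$p,
             ifelse(ve < vc, p_under, ifelse(vc < ve, p_over, al$p)))
    })
}

#' Urn randomization for unequal allocation
#'
#' An urn starts with `init_e` experimental and `init_c` control balls; each
#' patient is assigned the arm of a ball drawn (with replacement) from the
#' urn. After a control assignment, `add_e_on_control` experimental balls are
#' added; after an experimental assignment, `add_c_on_experimental` control
#' balls are added.
#'
#' With a 2:1 start `(2, 1)` and the default `add_e_on_control = 2`, the
#' unconditional experimental-assignment probabilities converge to about
#' 0.586, not 2/3: the design fails the constant-probability requirement.
#' Setting `add_e_on_control = 4` repairs the drift (limit exactly 2/3).
#'
#' @param init_e,init_c initial ball counts; the allocation target is
#'   `init_e : init_c`.
#' @param add_e_on_control experimental balls added after a control
#'   assignment.
#' @param add_c_on_experimental control balls added after an experimental
#'   assignment.
#' @return A `"rand_design"` object.
#' @examples
#' round(limiting_prob(urn_design(2, 1, add_e_on_control = 2)), 3)  # 0.586
#' round(limiting_prob(urn_design(2, 1, add_e_on_control = 4)), 3)  # 0.667
#' @export
urn_design <- function(init_e = 2, init_c = 1, add_e_on_control = 2,
                       add_c_on_experimental = 1) {
  al <- alloc_spec(c(init_e, init_c))
  if (add_e_on_control < 0 || add_c_on_experimental < 0)
    stop("ball additions must be nonnegative")
  .count_design(
    sprintf("urn (%d E, %d C; +%dE on C, +%dC on E)", init_e, init_c,
            add_e_on_control, add_c_on_experimental),
    al, list(init = c(init_e, init_c),
             add = c(add_e_on_control, add_c_on_experimental)),
    # urn composition is a function of the arm counts so far
    rule = function(ne, nc) {
      E <- init_e + add_e_on_control * nc
      C <- init_c + add_c_on_experimental * ne
      E / (E + C)
    })
}

#' Balanced multi-arm designs for use with [sequential_combine_design()]
#'
#' `multiarm_complete_design()` assigns each of `arms` arms independently with
#' probability `1/arms`. `multiarm_blocks_design()` draws assignments without
#' replacement from blocks containing `block_size/arms` slots per arm, within
#' strata. Both treat the arms symmetrically (label-permutation invariant),
#' which is the property that makes arm-combining preserve the constant
#' assignment probability.
#'
#' @param arms number of arms (>= 2).
#' @param block_size block length, a multiple of `arms`.
#' @return An object of class `"multiarm_design"`.
#' @export
multiarm_complete_design <- function(arms = 3) {
  arms <- as.integer(arms)
  structure(list(
    name = sprintf("%d-arm complete", arms), arms = arms,
    init_state = NULL,
    prob_fn = function(state, stratum) rep(1 / arms, arms),
    advance = function(state, stratum, arm) NULL,
    state_key = function(state) "",
    kind = "complete", stratified = FALSE), class = "multiarm_design")
}

#' @rdname multiarm_complete_design
#' @export
multiarm_blocks_design <- function(arms = 3, block_size = arms) {
  arms <- as.integer(arms)
  if (block_size < arms || block_size %% arms != 0)
    stop("'block_size' must be a positive multiple of 'arms'")
  block_size <- as.integer(block_size)
  per <- block_size %/% arms
  current <- function(state, s) {
    st <- state[[s]]
    if (is.null(st) || sum(st) == 0L) rep(per, arms) else st
  }
  structure(list(
    name = sprintf("%d-arm permuted blocks, block size %d", arms, block_size),
    arms = arms, init_state = list(), block_size = block_size,
    prob_fn = function(state, stratum) {
      st <- current(state, as.character(stratum))
      st / sum(st)
    },
    advance = function(state, stratum, arm) {
      s <- as.character(stratum)
      st <- current(state, s)
      st[arm] <- st[arm] - 1L
      if (sum(st) == 0L) state[[s]] <- NULL else state[[s]] <- st
      state
    },
    state_key = function(state) {
      if (!length(state)) return(".")
      nm <- sort(names(state))
      paste(nm, vapply(state[nm], paste, character(1), collapse = "/"),
            sep = ":", collapse = ";")
    },
    kind = "blocks", stratified = TRUE), class = "multiarm_design")
}

#' @export
print.multiarm_design <- function(x, ...) {
  cat(sprintf("Multi-arm design: %s\n", x$name)); invisible(x)
}

#' Unequal allocation by combining balanced arms
#'
#' Performs a symmetric balanced randomization to `r1 + r2` arms and labels
#' the first `r1` arms "experimental" and the remaining `r2` arms "control".
#' Because the inner design treats its arms symmetrically, every patient's
#' unconditional probability of an experimental assignment is exactly
#' `p = r1/(r1+r2)`: this construction achieves unequal allocation while
#' preserving the constant-probability requirement that threshold biased
#' coins, marginal-balance minimization and naive urn generalizations
#' violate.
#'
#' @param inner a `"multiarm_design"` with `r1 + r2` arms.
#' @inheritParams alloc_spec
#' @return A `"rand_design"` object. Transitions are stochastic given the
#'   binary assignment (the inner arm is not determined by it); the exact
#'   engine and samplers handle this transparently.
#' @examples
#' d <- sequential_combine_design(multiarm_blocks_design(3, 3), c(2, 1))
#' marginal_probs(d, 6)  # 2/3 for every patient
#' @export
sequential_combine_design <- function(inner, ratio = c(2, 1)) {
  al <- alloc_spec(ratio)
  k <- al$r1 + al$r2
  if (!inherits(inner, "multiarm_design"))
    stop("'inner' must be a multiarm_design")
  if (inner$arms != k)
    stop(sprintf("inner design must have r1 + r2 = %d arms", k))
  idx_e <- seq_len(al$r1); idx_c <- al$r1 + seq_len(al$r2)
  new_rand_design(
    sprintf("combined %d:%d via %s", al$r1, al$r2, inner$name),
    al, list(inner = inner),
    init_state = inner$init_state,
    prob_fn = function(state, stratum)
      sum(inner$prob_fn(state, stratum)[idx_e]),
    advance = function(state, stratum, delta) {
      pv <- inner$prob_fn(state, stratum)
      arms <- if (delta == 1L) idx_e else idx_c
      w <- pv[arms]
      keep <- w > 0
      arms <- arms[keep]; w <- w[keep] / sum(w[keep])
      lapply(seq_along(arms), function(j)
        list(state = inner$advance(state, stratum, arms[j]), w = w[j]))
    },
    state_key = inner$state_key,
    subclass = "seq_combine_design", stratified = inner$stratified)
}

#' Pocock-Simon minimization (1:1)
#'
#' Covariate-adaptive randomization over several stratification factors. For
#' the current patient, the hypothetical post-assignment imbalance of each
#' arm is the weighted sum, over the factors, of the absolute difference in
#' arm counts among previous patients sharing the patient's level of that
#' factor. The arm with the smaller imbalance is assigned with probability
#' `bias_prob`; ties use a fair coin. The rule is symmetric in the arm
#' labels, so every patient's unconditional assignment probability is 1/2.
#'
#' @param factors character vector naming the stratification factors. The
#'   engines must then be given `strata` as a data frame with these columns.
#' @param weights per-factor weights (recycled).
#' @param bias_prob probability of assigning the imbalance-reducing arm.
#' @return A `"rand_design"` object.
#' @export
pocock_simon_design <- function(factors, weights = 1, bias_prob = 3/4) {
  if (!length(factors)) stop("at least one stratification factor is required")
  if (bias_prob <= 1/2 || bias_prob >= 1)
    stop("'bias_prob' must be in (1/2, 1)")
  weights <- rep_len(weights, length(factors))
  names(weights) <- factors
  al <- alloc_spec(c(1, 1))

  counts_for <- function(state, f, lev) {
    key <- paste0(f, "=", lev)
    if (is.null(state[[key]])) c(0L, 0L) else state[[key]]
  }
  imbalance <- function(state, stratum, delta) {
    tot <- 0
    for (f in factors) {
      ct <- counts_for(state, f, stratum[[f]])
      ct[2L - delta] <- ct[2L - delta] + 1L  # slot 1 = E, slot 2 = C
      tot <- tot + weights[[f]] * abs(ct[1] - ct[2])
    }
    tot
  }
  new_rand_design(
    "Pocock-Simon minimization 1:1", al,
    list(factors = factors, weights = weights, bias_prob = bias_prob),
    init_state = list(),
    prob_fn = function(state, stratum) {
      ve <- imbalance(state, stratum, 1L)
      vc <- imbalance(state, stratum, 0L)
      if (ve < vc) bias_prob else if (vc < ve) 1 - bias_prob else 0.5
    },
    advance = function(state, stratum, delta) {
      for (f in factors) {
        key <- paste0(f, "=", stratum[[f]])
        ct <- counts_for(state, f, stratum[[f]])
        ct[2L - delta] <- ct[2L - delta] + 1L
        state[[key]] <- ct
      }
      .det(state)
    },
    state_key = function(state) {
      if (!length(state)) return(".")
      nm <- sort(names(state))
      paste(nm, vapply(state[nm], paste, character(1), collapse = "/"),
            sep = ":", collapse = ";")
    },
    subclass = "pocock_simon_design", stratified = TRUE)
}
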