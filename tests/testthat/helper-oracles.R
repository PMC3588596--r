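# Independent history-based re-derivations of the dynamic assignment rules.
# These deliberately avoid the package's state abstraction and DP engine:
# each rule is a function of the raw assignment history, and expectations
# are taken by enumerating every assignment path.

rule_biased_coin_21 <- function(hist) {
  if (!length(hist)) return(2/3)
  ne <- sum(hist); nc <- length(hist) - ne
  d <- ne / 2 - nc
  if (d <= -1) 0.9 else if (d >= 1) 0.2 else 2/3
}

rule_marginal_balance_21 <- function(hist) {
  if (!length(hist)) return(2/3)
  ne <- sum(hist); nc <- length(hist) - ne
  met <- function(e, c) abs(e / 2 - c)
  ve <- met(ne + 1, nc); vc <- met(ne, nc + 1)
  if (ve < vc) 0.9 else if (vc < ve) 0.2 else 2/3
}

rule_urn_21 <- function(add_e) function(hist) {
  E <- 2 + add_e * sum(hist == 0)
  C <- 1 + sum(hist == 1)
  E / (E + C)
}

rule_efron <- function(bias = 2/3) function(hist) {
  if (!length(hist)) return(0.5)
  d <- sum(hist) - (length(hist) - sum(hist))
  if (d <= -1) bias else if (d >= 1) 1 - bias else 0.5
}

# all 2^n assignment paths with their probabilities under a history rule
oracle_paths <- function(rule, n) {
  delta <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  colnames(delta) <- NULL
  prob <- apply(delta, 1, function(d) {
    pr <- 1
    for (i in seq_len(n)) {
      p <- rule(d[seq_len(i - 1)])
      pr <- pr * if (d[i] == 1) p else 1 - p
    }
    pr
  })
  keep <- prob > 0
  list(delta = delta[keep, , drop = FALSE], prob = prob[keep])
}

oracle_marginals <- function(rule, n) {
  o <- oracle_paths(rule, n)
  colSums(o$delta * o$prob)
}

# exact moments of a functional f(delta) from an enumerated sequence table
enum_expect <- function(enum, f) {
  vals <- apply(enum$delta, 1, f)
  sum(vals * enum$prob)
}
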