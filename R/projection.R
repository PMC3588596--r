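#' Residual-maker projection for a covariate matrix
#'
#' Builds the covariate matrix `X` (which must contain the intercept in its
#' column space) and the symmetric idempotent residual-maker
#' `M = I - X (X'X)^{-1} X'` that projects onto the orthogonal complement of
#' the columns of `X`. All randomization-model quantities -- the adjusted
#' treatment-effect estimator, its variance, and the ancillary statistic
#' `delta' M delta` -- are defined through `M`.
#'
#' Supply either a one-sided `formula` plus `data` (factors are encoded by
#' [stats::model.matrix()]; the resulting `M` does not depend on the factor
#' coding), an explicit numeric matrix `x`, or just `n` for an
#' intercept-only analysis.
#'
#' @param formula one-sided formula of covariate terms, e.g. `~ s1 + s2`.
#' @param data data frame providing the terms.
#' @param x alternatively, a full-column-rank numeric matrix of covariates.
#' @param n alternatively, the number of patients for an intercept-only `X`.
#' @param tol rank tolerance for the QR decomposition.
#' @return An object of class `"projection"`: list with the `n x n` matrix
#'   `M`, the covariate matrix `X`, its rank `q`, and `n`.
#' @examples
#' pr <- residual_projection(n = 10)
#' delta <- rep(c(1, 0), c(8, 2))
#' ancillary(pr, delta)  # (1/8 + 1/2)^{-1} = 1.6
#' @export
residual_projection <- function(formula = NULL, data = NULL, x = NULL,
                                n = NULL, tol = 1e-10) {
  if (!is.null(formula)) {
    X <- stats::model.matrix(formula, data = data)
  } else if (!is.null(x)) {
    X <- as.matrix(x)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  } else if (!is.null(n)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else stop("supply 'formula' + 'data', 'x', or 'n'")
  n <- nrow(X)
  qrX <- qr(X, tol = tol)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  # intercept requirement: 1 must lie in the column space of X
  ones <- rep(1, n)
  if (sum(qr.resid(qrX, ones)^2) > tol * n)
    stop("the intercept must lie in the column space of X")
  Q <- qr.Q(qrX)
  M <- diag(n) - tcrossprod(Q)
  structure(list(M = (M + t(M)) / 2, X = X, q = qrX$rank, n = n),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("Residual projection: n = %d, rank(X) = %d [%s]\n",
              x$n, x$q, paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Ancillary statistic of an assignment vector
#'
#' Evaluates the quadratic form `delta' M delta`, the ancillary statistic of
#' the randomization model: its distribution is free of the treatment effect
#' and, for simple covariate matrices, it is a function of the treatment
#' group sizes within strata (e.g. `(1/n0 + 1/n1)^{-1}` for an
#' intercept-only `X`). Conditional inference is indexed by its value.
#'
#' @param projection a [`projection`][residual_projection].
#' @param delta 0/1 assignment vector, or a matrix with one column per
#'   assignment vector.
#' @return A nonnegative scalar (or vector, one value per column).
#' @export
ancillary <- function(projection, delta) {
  M <- projection$M
  if (is.matrix(delta)) {
    stopifnot(nrow(delta) == nrow(M))
    return(colSums(delta * (M %*% delta)))
  }
  stopifnot(length(delta) == nrow(M))
  drop(crossprod(delta, M %*% delta))
}

## internal quadratic-form helpers; A, B symmetric
.trAB <- function(A, B) sum(A * B)
.quad <- function(v, A) drop(crossprod(v, A %*% v))
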