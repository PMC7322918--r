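# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Cholesky solve with a one-shot ridge repair on the correlation diagonal.
# V = D R D with D = diag(se); if V is not positive definite, R's diagonal
# gets +ridge and V is rebuilt once.  Returns list(V, chol) or errors.
chol_with_ridge <- function(se, R, ridge = 1e-6) {
  D <- diag(se, nrow = length(se))
  V <- D %*% R %*% D
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    V <- D %*% (R + diag(ridge, nrow(R))) %*% D
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) stop("covariance matrix singular after ridge repair")
  }
  list(V = V, chol = ch)
}

# Solve A x = b given chol(A).
chol_solve <- function(ch, b) backsolve(ch, backsolve(ch, b, transpose = TRUE))

#' Convert methylation beta values to M-values and back
#'
#' M = log2(beta / (1 - beta)).  Beta values at the boundaries are clipped
#' to `eps` / `1 - eps` before the log to keep M finite.
#'
#' @param beta Numeric vector or matrix of beta values in \[0, 1\].
#' @param m Numeric vector or matrix of M-values.
#' @param eps Boundary clip applied before the logit.
#' @return Transformed values of the same shape.
#' @export
beta_to_mval <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_mval
#' @export
mval_to_beta <- function(m) 2^m / (1 + 2^m)

# Two-sided normal p-value from an estimate and its SE.
z_pvalue <- function(est, se) 2 * stats::pnorm(-abs(est / se))
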