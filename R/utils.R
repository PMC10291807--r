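# Internal numerical helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Ridge-stabilized correlation matrix
#'
#' Adds `eps` to the diagonal and renormalizes back to a correlation matrix,
#' so unit diagonal and exact zero off-diagonals are preserved while
#' near-singular matrices become safely invertible.
#' @keywords internal
ridge_cor <- function(R, eps = 0.01) {
  if (eps <= 0) return(R)
  R <- R + diag(eps, nrow(R))
  stats::cov2cor(R)
}

# Column-standardize a dosage matrix; constant columns error by default.
#' @keywords internal
standardize_columns <- function(X, allow_constant = FALSE) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  if (any(sdv == 0)) {
    if (!allow_constant)
      stop("constant dosage column(s): ",
           paste(colnames(X)[sdv == 0], collapse = ", "), call. = FALSE)
    sdv[sdv == 0] <- 1
  }
  sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
}

# Derive a stream of child seeds from one integer seed, kept below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided normal p-value from a z-score, stable in the far tail (log scale
# kept positive via pnorm lower tail).
#' @keywords internal
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))
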