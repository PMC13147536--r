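#' Randomized Nystrom preconditioner
#'
#' Builds a low-rank Nystrom approximation \eqn{U \Lambda U^T \approx A}
#' of a symmetric positive-semidefinite operator from a Gaussian sketch
#' (with shift stabilization), and returns the preconditioner
#' \deqn{M^{-1} x = U (\Lambda + \mu)^{-1} U^T x +
#'       \frac{1}{\mu} (x - U U^T x),}
#' a symmetric positive-definite operator that approximately inverts
#' \eqn{A + \mu I}.  Intended for \eqn{V = \tau^2 B + \sigma_\epsilon^2 I},
#' whose spectrum is bounded below by \eqn{\sigma_\epsilon^2}; the natural
#' shift is therefore the current \eqn{\sigma_\epsilon^2}.
#'
#' If `rank >= dim` the operator is materialized by applying it to the
#' identity and inverted exactly (test-scale fallback).
#'
#' @param A a [linop()], symmetric positive semidefinite.
#' @param rank sketch rank (number of Gaussian test vectors).
#' @param shift positive spectral shift \eqn{\mu}.
#' @param seed integer seed for the Gaussian sketch.
#' @return a [linop()] applying \eqn{M^{-1}}; attributes `"U"` and
#'   `"lambda"` expose the approximation factors.
#' @export
nystrom_preconditioner <- function(A, rank, shift, seed = NULL) {
  stopifnot(rank >= 1, shift > 0)
  fac <- nystrom_factors(A, rank, seed)
  precond_from_factors(fac, shift = shift)
}

# Low-rank Nystrom approximation U diag(lambda) U' of a symmetric PSD
# operator.  Computed once per operator; preconditioners for any spectral
# shift (or any tau2 * A + sigma2 * I combination) derive from it without
# further operator applications.
nystrom_factors <- function(A, rank, seed = NULL) {
  n <- A$dim
  if (rank >= n) {
    # test-scale fallback: materialize and eigendecompose exactly
    M <- linop_apply(A, diag(n))
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    return(list(U = eg$vectors, lambda = pmax(eg$values, 0), exact = TRUE))
  }
  Om <- with_seed(seed, matrix(rnorm(n * rank), n, rank))
  Om <- qr.Q(qr(Om))                       # orthonormal sketch
  Y <- linop_apply(A, Om)
  nu <- .Machine$double.eps * sqrt(n) * max(sqrt(colSums(Y^2)), 1e-300)
  Ynu <- Y + nu * Om
  G <- crossprod(Om, Ynu)
  G <- (G + t(G)) / 2
  R <- tryCatch(chol(G),
                error = function(e) chol(G + (nu + 1e-12) * diag(rank)))
  Bm <- t(forwardsolve(t(R), t(Ynu)))      # Ynu %*% R^{-1}
  sv <- svd(Bm, nv = 0)
  list(U = sv$u, lambda = pmax(sv$d^2 - nu, 0), exact = FALSE)
}

# Preconditioner U (scale*lambda + shift)^{-1} U' + (1/shift)(I - U U')
# for scale * A + shift-part I, from cached factors of A.
precond_from_factors <- function(fac, shift, scale = 1) {
  stopifnot(shift > 0)
  U <- fac$U
  d <- scale * fac$lambda + shift
  op <- linop(nrow(U), function(x) {
    Utx <- crossprod(U, x)
    U %*% (Utx / d) + (x - U %*% Utx) / shift
  })
  attr(op, "U") <- U
  attr(op, "lambda") <- fac$lambda
  op
}
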