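#' Preconditioned conjugate gradient solver
#'
#' Solves \eqn{A x = b} for a symmetric positive-definite operator, to a
#' relative residual tolerance, optionally with a symmetric
#' positive-definite preconditioner \eqn{M^{-1}}.  Multiple right-hand
#' sides are solved simultaneously: matvecs are batched over the columns
#' that have not yet converged, and each column carries its own step
#' sizes.  Iterations start from the zero vector.
#'
#' @param A a [linop()], symmetric positive definite (at least on the span
#'   of the right-hand sides).
#' @param b vector or matrix of right-hand sides.
#' @param tol relative residual tolerance \eqn{\|Ax - b\| / \|b\|}.
#' @param precond optional [linop()] applying \eqn{M^{-1}}.
#' @param max_iter iteration cap; exceeding it is an error carrying the
#'   worst relative residual reached.
#' @return solution with the shape of `b`; attribute `"iterations"` holds
#'   the iteration count.
#' @export
conjugate_gradient <- function(A, b, tol = 1e-5, precond = NULL,
                               max_iter = 1000L) {
  vec <- is.null(dim(b))
  b <- as.matrix(b)
  if (nrow(b) != A$dim) stop("dimension mismatch")
  if (!all(is.finite(b))) stop("right-hand side contains non-finite values")
  n <- nrow(b); k <- ncol(b)
  x <- matrix(0, n, k)
  bnorm <- sqrt(colSums(b^2))
  active <- which(bnorm > 0)          # b = 0 columns solve to x = 0
  r <- b[, active, drop = FALSE]
  z <- if (is.null(precond)) r else linop_apply(precond, r)
  p <- z
  rz <- colSums(r * z)
  iter <- 0L
  while (length(active)) {
    if (iter >= max_iter) {
      rel <- sqrt(colSums(r^2)) / bnorm[active]
      cond <- simpleError(paste0(
        "conjugate gradient did not converge in ", max_iter,
        " iterations (worst relative residual ",
        format(max(rel), digits = 3), ")"))
      cond$residual <- max(rel)
      stop(cond)
    }
    Ap <- linop_apply(A, p)
    alpha <- rz / colSums(p * Ap)
    x[, active] <- x[, active] + sweep(p, 2, alpha, "*")
    r <- r - sweep(Ap, 2, alpha, "*")
    iter <- iter + 1L
    done <- sqrt(colSums(r^2)) <= tol * bnorm[active]
    if (any(done)) {
      keep <- !done
      active <- active[keep]
      if (!length(active)) break
      r <- r[, keep, drop = FALSE]
      p <- p[, keep, drop = FALSE]
      rz <- rz[keep]
    }
    z <- if (is.null(precond)) r else linop_apply(precond, r)
    rz_new <- colSums(r * z)
    p <- z + sweep(p, 2, rz_new / rz, "*")
    rz <- rz_new
  }
  attr(x, "iterations") <- iter
  if (vec) {
    out <- drop(x)
    attr(out, "iterations") <- iter
    out
  } else x
}
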