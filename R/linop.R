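# Matrix-free symmetric linear operators: a dimension plus a batched
# apply.  All operators used in the package (B, V = tau2*B + sigma2*I,
# preconditioners, composites) are exposed through this contract.

#' Create a matrix-free linear operator
#'
#' @param dim dimension of the (square) operator.
#' @param apply a function taking an n x k matrix and returning the n x k
#'   matrix of products; it must act column-wise (batched apply equals
#'   column-by-column apply).
#' @return an object of class `linop`.
#' @export
linop <- function(dim, apply) {
  stopifnot(is.function(apply), dim >= 1)
  structure(list(dim = as.integer(dim), apply = apply), class = "linop")
}

#' Apply a linear operator
#'
#' @param op a [linop()].
#' @param x a vector of length `op$dim` or a matrix with `op$dim` rows.
#' @return product with the same shape as `x`.
#' @export
linop_apply <- function(op, x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (nrow(x) != op$dim) stop("dimension mismatch: operator is ", op$dim)
  out <- op$apply(x)
  if (vec) drop(out) else out
}

#' @export
print.linop <- function(x, ...) {
  cat("<linop> dim", x$dim, "\n")
  invisible(x)
}

#' Wrap a dense symmetric matrix as an operator
#' @param M symmetric matrix.
#' @export
dense_operator <- function(M) {
  M <- as.matrix(M)
  linop(nrow(M), function(x) M %*% x)
}

#' Branch-GRM operator over individuals
#'
#' Wraps [grm_matvec()] as a [linop()], optionally centered and rescaled:
#' the operator computes \eqn{B w / scale} (or the centered analogue).
#' Dividing by `4 * total_root_area(arg)` puts the GRM on the unit scale
#' used when phenotypes are simulated with [simulate_phenotypes()].
#'
#' @param arg an [arg_data()] object.
#' @param centered center rows and columns (projection \eqn{P_N}).
#' @param scale positive scalar divisor applied to the GRM.
#' @export
branch_grm_operator <- function(arg, centered = FALSE, scale = 1) {
  stopifnot(scale > 0)
  N <- n_individuals(arg)
  force(centered)
  linop(N, function(x) grm_matvec(arg, x, centered = centered) / scale)
}

# V = tau2 * B + sigma2 * I for a GRM operator B
covariance_operator <- function(B, tau2, sigma2) {
  linop(B$dim, function(x) tau2 * linop_apply(B, as.matrix(x)) + sigma2 * x)
}
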