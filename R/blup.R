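#' BLUP prediction of genetic values
#'
#' Empirical best linear unbiased prediction under the fitted ARG-LMM:
#' \deqn{\hat g_n = \hat\tau^2 B_{n,o}
#'   (\hat\tau^2 B_{o,o} + \hat\sigma_\epsilon^2 I)^{-1} (y_o - X_o \hat b),}
#' where `o` indexes the phenotyped (observed) individuals and `n` the
#' prediction targets (the two sets may overlap).  The shared solve
#' against the observed covariance is done once by preconditioned
#' conjugate gradient; the cross-covariance product uses one implicit
#' submatrix matvec (scatter onto the observed set, full product, gather
#' the targets).  Optional conditional variances follow the Gaussian
#' conditioning identity \eqn{\Sigma_{xx} - \Sigma_{xz}\Sigma_{zz}^{-1}
#' \Sigma_{zx}} and require one solve per target, so are guarded to small
#' target sets.
#'
#' @param arg an [arg_data()] object (or `NULL` to reuse the operator in
#'   `fit`, in which case index sets refer to the fitted individuals).
#' @param fit a [fit_reml()] result carrying \eqn{\hat\tau^2},
#'   \eqn{\hat\sigma_\epsilon^2} and the GRM scale.
#' @param y_o phenotypes of the observed individuals (length
#'   `length(obs_index)`).
#' @param X covariate matrix over all individuals (rows indexed like the
#'   ARG's individuals), including an intercept.
#' @param obs_index,target_index 1-based individual index sets.
#' @param with_variance also return the conditional covariance matrix of
#'   the targets (dense in the target set; guarded).
#' @param max_variance_targets guard for `with_variance`.
#' @return an object of class `blup_result`: `predicted` (one value per
#'   target), optionally `conditional_variance`, plus the index sets and
#'   the GLS coefficients used.
#' @export
predict_blup <- function(arg, fit, y_o, X = NULL, obs_index, target_index,
                         with_variance = FALSE, max_variance_targets = 2000) {
  shared <- blup_shared_solve(arg, fit, y_o, X, obs_index)
  target_index <- check_blup_index(target_index, shared$N)
  tau2 <- fit$tau2
  ghat <- tau2 * shared$sub_mv(shared$r, rows = target_index,
                               cols = shared$obs_index)
  out <- list(predicted = drop(as.matrix(ghat)),
              obs_index = shared$obs_index, target_index = target_index,
              coefficients = shared$bhat, converged = fit$converged)
  if (with_variance) {
    n_t <- length(target_index)
    if (n_t > max_variance_targets)
      stop("conditional variances requested for ", n_t,
           " targets (guard is ", max_variance_targets, ")")
    # Sigma_xx = tau2 B_nn ; Sigma_xz = tau2 B_no
    Id <- diag(n_t)
    B_nn <- tau2 * as.matrix(
      shared$sub_mv(Id, rows = target_index, cols = target_index))
    C_on <- tau2 * as.matrix(
      shared$sub_mv(Id, rows = shared$obs_index, cols = target_index))
    E <- shared$solve_V(C_on)
    cv <- B_nn - crossprod(C_on, E)
    out$conditional_variance <- (cv + t(cv)) / 2
  }
  class(out) <- "blup_result"
  out
}

#' Predict a general linear combination of sub-edge effects
#'
#' Generic Gaussian conditioning with zero prior mean: any quantity
#' \eqn{x} with known cross-covariance to the observed phenotypes is
#' predicted as `cross_cov(r)` where \eqn{r = (\hat\tau^2 B_{o,o} +
#' \hat\sigma_\epsilon^2 I)^{-1}(y_o - X_o\hat b)} is the shared BLUP
#' solve.  Supplying the cross-covariance operator
#' \eqn{v \mapsto \hat\tau^2 B_{n,o} v} reproduces [predict_blup()];
#' restricting the covariance to a genomic window yields window-wise
#' genetic values that sum to the genome-wide BLUP.
#'
#' @inheritParams predict_blup
#' @param cross_cov function mapping a vector over observed individuals to
#'   \eqn{\Sigma_{xz} v}.
#' @return `cross_cov(r)`.
#' @export
predict_linear_combination <- function(arg, fit, y_o, X = NULL, obs_index,
                                       cross_cov) {
  shared <- blup_shared_solve(arg, fit, y_o, X, obs_index)
  cross_cov(shared$r)
}

#' @export
print.blup_result <- function(x, ...) {
  cat("BLUP predictions for", length(x$target_index), "individuals from",
      length(x$obs_index), "observed phenotypes\n")
  print(summary(x$predicted))
  invisible(x)
}

# -- internal helpers ------------------------------------------------------

check_blup_index <- function(i, N) {
  i <- as.integer(i)
  if (any(i < 1 | i > N)) stop("index out of range")
  i
}

# One-time solve r = (tau2 B_oo + s2 I)^{-1} (y_o - X_o bhat), shared by
# all predictions from the same observed set.
blup_shared_solve <- function(arg, fit, y_o, X, obs_index) {
  if (!length(obs_index)) stop("obs_index is empty")
  if (!fit$converged)
    warning("variance components come from a non-converged fit; ",
            "predictions are flagged")
  N <- if (inherits(arg, "arg_data")) n_individuals(arg) else fit$B$dim
  obs_index <- check_blup_index(obs_index, N)
  stopifnot(length(y_o) == length(obs_index))
  sub_mv <- blup_submatrix_fn(arg, fit)
  if (is.null(X)) X <- matrix(1, N, 1)
  X_o <- as.matrix(X)[obs_index, , drop = FALSE]
  tau2 <- fit$tau2
  s2 <- fit$sigma_e2
  n_o <- length(obs_index)
  V_oo <- linop(n_o, function(x)
    tau2 * as.matrix(sub_mv(x, rows = obs_index, cols = obs_index)) + s2 * x)
  cfg <- fit$config
  # positive shift even when sigma_e2 was estimated at (or clamped to) zero
  shift <- max(s2, 1e-10 * max(tau2, 1))
  precond <- nystrom_preconditioner(V_oo, rank = min(cfg$nystrom_rank, n_o),
                                    shift = shift, seed = cfg$seed)
  solve_V <- function(b) conjugate_gradient(V_oo, b, tol = cfg$cg_tol,
                                            precond = precond,
                                            max_iter = max(1000L, n_o))
  ViX <- solve_V(X_o)
  XtViX <- crossprod(X_o, ViX)
  Viy <- solve_V(as.numeric(y_o))
  bhat <- drop(solve(XtViX, crossprod(X_o, Viy)))
  r <- drop(Viy - ViX %*% solve(XtViX, crossprod(X_o, Viy)))
  list(r = r, bhat = bhat, solve_V = solve_V, sub_mv = sub_mv,
       obs_index = obs_index, N = N)
}

# submatrix matvec: scatter onto cols, full (scaled) product, gather rows
blup_submatrix_fn <- function(arg, fit) {
  if (inherits(arg, "arg_data")) {
    scale <- fit$grm_scale
    function(x, rows, cols)
      as.matrix(grm_matvec(arg, as.matrix(x), rows = rows,
                           cols = cols)) / scale
  } else {
    B <- fit$B
    function(x, rows, cols) {
      x <- as.matrix(x)
      full <- matrix(0, B$dim, ncol(x))
      full[cols, ] <- x
      as.matrix(linop_apply(B, full))[rows, , drop = FALSE]
    }
  }
}
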