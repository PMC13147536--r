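#' Configuration for stochastic AI-REML
#'
#' Default values reproduce the method's standard hyperparameters:
#' conjugate-gradient tolerance \code{1e-5}, 50 test vectors for gradient
#' trace estimation, Nystrom preconditioner rank 500, 50 test vectors for
#' the randomized Haseman-Elston initializer, relative-change convergence
#' threshold 0.05, and 15 additional averaging steps after convergence
#' triggers.
#'
#' @param cg_tol conjugate gradient relative-residual tolerance.
#' @param n_trace_vectors test vectors per trace in the gradient.
#' @param nystrom_rank rank of the randomized Nystrom preconditioner.
#' @param n_he_vectors test vectors for the randomized HE initializer.
#' @param rel_change_threshold relative change of both components below
#'   which the stopping rule triggers.
#' @param min_post_steps iterations run (and averaged) after triggering.
#' @param max_iter hard iteration cap.
#' @param seed master seed; all per-iteration randomness is derived from it.
#' @return a list of class `reml_config`.
#' @export
reml_config <- function(cg_tol = 1e-5, n_trace_vectors = 50L,
                        nystrom_rank = 500L, n_he_vectors = 50L,
                        rel_change_threshold = 0.05, min_post_steps = 15L,
                        max_iter = 100L, seed = NULL) {
  structure(list(cg_tol = cg_tol, n_trace_vectors = as.integer(n_trace_vectors),
                 nystrom_rank = as.integer(nystrom_rank),
                 n_he_vectors = as.integer(n_he_vectors),
                 rel_change_threshold = rel_change_threshold,
                 min_post_steps = as.integer(min_post_steps),
                 max_iter = as.integer(max_iter), seed = seed),
            class = "reml_config")
}

# Resolve the GRM argument: an arg_data (with optional scale) or a linop.
as_grm_operator <- function(arg, grm_scale = 1) {
  if (inherits(arg, "linop")) arg
  else if (inherits(arg, "arg_data"))
    branch_grm_operator(arg, scale = grm_scale)
  else stop("expected an arg_data or linop for the GRM")
}

#' REML working state
#'
#' Bundles the data (y, X), the GRM operator B, the current variance
#' components, and the solver caches (the V operator, its Nystrom
#' preconditioner, and \eqn{V^{-1}X}) needed to multiply by the REML
#' projection \eqn{P = V^{-1} - V^{-1}X(X^T V^{-1}X)^{-1}X^T V^{-1}}.
#'
#' @param B a [linop()] for the GRM (see [branch_grm_operator()]).
#' @param y phenotype vector.
#' @param X covariate matrix (including an intercept), full column rank.
#' @param tau2,sigma_e2 current variance components.
#' @param config a [reml_config()].
#' @param precond_seed seed for the preconditioner sketch.
#' @return a list of class `reml_state`.
#' @export
reml_state <- function(B, y, X, tau2, sigma_e2, config = reml_config(),
                       precond_seed = NULL, grm_factors = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  N <- length(y)
  stopifnot(B$dim == N, nrow(X) == N)
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  if (ncol(X) >= N) stop("more covariates than observations")
  V <- covariance_operator(B, tau2, sigma_e2)
  # preconditioner for V composed from a (possibly cached) Nystrom sketch
  # of B: U(tau2*Lambda + sigma2)^-1 U' + (1/sigma2)(I - UU')
  if (is.null(grm_factors))
    grm_factors <- nystrom_factors(B, rank = min(config$nystrom_rank, N),
                                   seed = precond_seed)
  precond <- precond_from_factors(grm_factors, shift = sigma_e2,
                                  scale = tau2)
  st <- list(B = B, y = y, X = X, tau2 = tau2, sigma_e2 = sigma_e2,
             V = V, precond = precond, config = config, N = N, K = ncol(X))
  st$solve_V <- function(b) conjugate_gradient(
    V, b, tol = config$cg_tol, precond = precond,
    max_iter = max(1000L, N))
  ViXy <- st$solve_V(cbind(X, y))          # one batched solve for X and y
  st$ViX <- ViXy[, seq_len(ncol(X)), drop = FALSE]
  st$Viy <- ViXy[, ncol(X) + 1L]
  st$XtViX <- crossprod(X, st$ViX)
  class(st) <- "reml_state"
  st
}

#' Multiply by the REML projection matrix P
#'
#' Computes \eqn{Pv = V^{-1}v - V^{-1}X (X^T V^{-1}X)^{-1} X^T V^{-1} v}
#' with \eqn{V^{-1}} products by preconditioned conjugate gradient and the
#' \eqn{K \times K} system solved densely.  For `v = y` this equals
#' \eqn{V^{-1}(y - X\hat b)} with \eqn{\hat b} the GLS coefficients.
#'
#' @param state a [reml_state()].
#' @param v vector or matrix.
#' @export
project_P <- function(state, v) {
  vec <- is.null(dim(v))
  v <- as.matrix(v)
  Viv <- state$solve_V(v)
  attr(Viv, "iterations") <- NULL
  rc <- rcond(state$XtViX)
  if (!is.finite(rc) || rc < 1e-12)
    stop("X' V^-1 X is (numerically) singular: rank-deficient covariates")
  out <- Viv - state$ViX %*% solve(state$XtViX, crossprod(state$X, Viv))
  if (vec) drop(out) else out
}

#' Generalized least squares coefficients
#'
#' \eqn{\hat b = (X^T V^{-1} X)^{-1} X^T V^{-1} y} at the state's current
#' variance components.  With \eqn{V \propto I} this is ordinary least
#' squares.
#'
#' @param state a [reml_state()].
#' @export
gls_coefficients <- function(state) {
  drop(solve(state$XtViX, crossprod(state$X, state$Viy)))
}

# Py from the cached V^{-1}[X, y] solves: V^{-1}(y - X b-hat)
state_Py <- function(state) {
  bhat <- solve(state$XtViX, crossprod(state$X, state$Viy))
  drop(state$Viy - state$ViX %*% bhat)
}

#' Stochastic REML gradient
#'
#' The gradient of the (doubled, negated-log) restricted likelihood with
#' respect to \eqn{(\sigma_\epsilon^2, \tau^2)}:
#' \deqn{\nabla = (tr(P) - y^T P P y,\; tr(PB) - y^T P B P y).}
#' Quadratic forms are computed exactly through [project_P()].  Traces are
#' split as \eqn{tr(P) = tr(V^{-1}) - tr((X^TV^{-1}X)^{-1}X^TV^{-1}V^{-1}X)}
#' (and analogously for \eqn{tr(PB)}): the \eqn{K \times K} parts are
#' exact and \eqn{tr(V^{-1})}, \eqn{tr(V^{-1}B)} are estimated by
#' [xtrace()].
#'
#' @param state a [reml_state()].
#' @param seed seed for the trace test vectors.
#' @param tr_vinv,tr_vinv_b optional exact traces of \eqn{V^{-1}} and
#'   \eqn{V^{-1}B}, bypassing stochastic estimation (used by oracles).
#' @return named vector `c(sigma_e2 = ..., tau2 = ...)`; attribute
#'   `"trace_se"` carries the two trace standard errors.
#' @export
reml_gradient <- function(state, seed = NULL, tr_vinv = NULL,
                          tr_vinv_b = NULL) {
  Py <- state_Py(state)
  BPy <- linop_apply(state$B, Py)
  yPPy <- sum(Py^2)
  yPBPy <- sum(Py * BPy)
  m <- state$config$n_trace_vectors
  seeds <- derive_seeds(seed, 2)
  se <- c(0, 0)
  if (is.null(tr_vinv)) {
    Vi_op <- linop(state$N, function(x) state$solve_V(x))
    est <- xtrace(Vi_op, m, seeds[[1]])
    tr_vinv <- est$value
    se[1] <- est$stderr
  }
  if (is.null(tr_vinv_b)) {
    ViB_op <- linop(state$N, function(x)
      state$solve_V(linop_apply(state$B, x)))
    est <- xtrace(ViB_op, m, seeds[[2]])
    tr_vinv_b <- est$value
    se[2] <- est$stderr
  }
  XtViX_inv <- solve(state$XtViX)
  tr_P <- tr_vinv - sum(XtViX_inv * crossprod(state$ViX))
  BViX <- linop_apply(state$B, state$ViX)
  tr_PB <- tr_vinv_b - sum(XtViX_inv * crossprod(state$ViX, BViX))
  out <- c(sigma_e2 = tr_P - yPPy, tau2 = tr_PB - yPBPy)
  attr(out, "trace_se") <- se
  out
}

#' Average information matrix
#'
#' The 2x2 matrix with entries \eqn{y^T P \dot V_i P \dot V_j P y} for
#' \eqn{\dot V_{\sigma} = I}, \eqn{\dot V_{\tau} = B} (component order
#' \eqn{(\sigma_\epsilon^2, \tau^2)}).  All trace terms cancel in the
#' average of the observed Hessian and the Fisher information, so the
#' matrix is assembled from cached products of \eqn{Py}, \eqn{BPy} and
#' their projections, with no stochastic estimation.  It is symmetric
#' positive semidefinite, and the update
#' \eqn{\theta \leftarrow \theta - AI^{-1}\nabla} descends the restricted
#' likelihood objective.
#'
#' @param state a [reml_state()].
#' @return symmetric 2x2 matrix, rows/cols ordered
#'   (`sigma_e2`, `tau2`).
#' @export
average_information <- function(state) {
  Py <- state_Py(state)
  BPy <- linop_apply(state$B, Py)
  P2 <- project_P(state, cbind(Py, BPy))
  PPy <- P2[, 1]
  PBPy <- P2[, 2]
  ai_ss <- sum(Py * PPy)
  ai_st <- sum(Py * PBPy)
  ai_tt <- sum(BPy * PBPy)
  matrix(c(ai_ss, ai_st, ai_st, ai_tt), 2, 2,
         dimnames = list(c("sigma_e2", "tau2"), c("sigma_e2", "tau2")))
}

#' Randomized Haseman-Elston variance components
#'
#' Moment estimator obtained by residualizing the phenotype against the
#' covariates (ordinary least squares) and solving
#' \deqn{\begin{pmatrix} tr(B^2) & tr(B) \\ tr(B) & N \end{pmatrix}
#'       \begin{pmatrix} \tau^2 \\ \sigma_\epsilon^2 \end{pmatrix} =
#'       \begin{pmatrix} y^T B y \\ y^T y \end{pmatrix},}
#' with \eqn{tr(B)} and \eqn{tr(B^2)} estimated by [xtrace()].  Used to
#' initialize [fit_reml()] and exposed as an estimator in its own right.
#'
#' @param arg an [arg_data()] or a GRM [linop()].
#' @param y phenotype vector.
#' @param X covariate matrix including an intercept.
#' @param n_vectors test vectors for the trace estimates.
#' @param seed integer seed.
#' @param grm_scale GRM divisor (see [branch_grm_operator()]).
#' @param tr_b,tr_b2 optional exact traces, bypassing estimation.
#' @return list with `tau2`, `sigma_e2`.
#' @export
he_initialize <- function(arg, y, X, n_vectors = 50L, seed = NULL,
                          grm_scale = 1, tr_b = NULL, tr_b2 = NULL) {
  B <- as_grm_operator(arg, grm_scale)
  y <- as.numeric(y)
  X <- as.matrix(X)
  N <- length(y)
  r <- qr.resid(qr(X), y)
  seeds <- derive_seeds(seed, 2)
  if (is.null(tr_b)) tr_b <- xtrace(B, n_vectors, seeds[[1]])$value
  if (is.null(tr_b2)) {
    B2 <- linop(N, function(x) linop_apply(B, linop_apply(B, x)))
    tr_b2 <- xtrace(B2, n_vectors, seeds[[2]])$value
  }
  Br <- linop_apply(B, r)
  M <- matrix(c(tr_b2, tr_b, tr_b, N), 2, 2)
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-10)
    stop("Haseman-Elston system is singular (is the GRM proportional to ",
         "the identity?)")
  sol <- solve(M, c(sum(r * Br), sum(r^2)))
  list(tau2 = sol[1], sigma_e2 = sol[2])
}

#' Fit the ARG linear mixed model by stochastic AI-REML
#'
#' Estimates the variance components of
#' \eqn{y \sim N(Xb, \tau^2 B + \sigma_\epsilon^2 I)} by
#' average-information REML with stochastic gradients: quadratic forms are
#' exact (computed with implicit GRM products and preconditioned conjugate
#' gradients), traces are estimated by [xtrace()], and the AI matrix is
#' trace-free.  Iterations start from the randomized Haseman-Elston
#' estimate; once both components change by less than the relative
#' threshold, a fixed number of further iterations is run and their
#' average is returned.  Components are clamped below at
#' `1e-8 * var(y)` to keep \eqn{V} positive definite.
#'
#' @param arg an [arg_data()] or a GRM [linop()].
#' @param y phenotype vector over individuals.
#' @param X covariate matrix; an intercept column is prepended when absent.
#' @param config a [reml_config()].
#' @param grm_scale GRM divisor (see [branch_grm_operator()]); use
#'   `4 * total_root_area(arg)` to match [simulate_phenotypes()] scaling.
#' @param init optional list with `tau2`, `sigma_e2` starting values
#'   (default: Haseman-Elston).
#' @param verbose print per-iteration progress.
#' @return an object of class `reml_fit`: `tau2`, `sigma_e2` (averaged
#'   final estimates), `se` (from the inverse AI at the final state),
#'   `converged`, `n_iter`, `history` (per-iteration data frame),
#'   `he_init`, plus the GRM operator and data for downstream prediction.
#' @export
fit_reml <- function(arg, y, X = NULL, config = reml_config(),
                     grm_scale = 1, init = NULL, verbose = FALSE) {
  B <- as_grm_operator(arg, grm_scale)
  y <- as.numeric(y)
  if (!all(is.finite(y))) stop("y contains non-finite values")
  if (var(y) == 0) stop("phenotype is constant: variance components are ",
                        "not identifiable")
  N <- length(y)
  stopifnot(B$dim == N)
  if (is.null(X)) X <- matrix(1, N, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0)))
    X <- cbind(intercept = 1, X)
  floor_val <- 1e-8 * var(y)
  clamp <- function(th) pmax(th, floor_val)
  seeds <- derive_seeds(config$seed, 3L * config$max_iter + 2L)
  grm_factors <- nystrom_factors(B, rank = min(config$nystrom_rank, N),
                                 seed = seeds[[3L * config$max_iter + 2L]])
  if (is.null(init))
    init <- he_initialize(B, y, X, n_vectors = config$n_he_vectors,
                          seed = seeds[[1]])
  theta <- clamp(c(sigma_e2 = init$sigma_e2, tau2 = init$tau2))
  history <- vector("list", config$max_iter)
  post_left <- NA_integer_
  converged <- FALSE
  n_iter <- 0L
  window <- list()
  last_state <- NULL
  for (it in seq_len(config$max_iter)) {
    st <- reml_state(B, y, X, tau2 = theta[["tau2"]],
                     sigma_e2 = theta[["sigma_e2"]], config = config,
                     grm_factors = grm_factors)
    grad <- reml_gradient(st, seed = seeds[[3 * it]])
    AI <- average_information(st)
    step <- tryCatch(solve(AI, grad), error = function(e)
      solve(AI + diag(1e-10 * max(diag(AI), 1), 2), grad))
    theta_new <- clamp(theta - step)
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), floor_val))
    history[[it]] <- data.frame(
      iter = it, sigma_e2 = theta_new[["sigma_e2"]],
      tau2 = theta_new[["tau2"]],
      grad_sigma_e2 = grad[["sigma_e2"]], grad_tau2 = grad[["tau2"]],
      ai_ss = AI[1, 1], ai_st = AI[1, 2], ai_tt = AI[2, 2],
      rel_change = rel,
      trace_se_vinv = attr(grad, "trace_se")[1],
      trace_se_vinv_b = attr(grad, "trace_se")[2])
    if (verbose)
      message(sprintf(
        "iter %3d: sigma_e2 = %.6g, tau2 = %.6g, |grad| = %.3g, rel = %.3g",
        it, theta_new[["sigma_e2"]], theta_new[["tau2"]],
        sqrt(sum(grad^2)), rel))
    theta <- theta_new
    n_iter <- it
    last_state <- st
    if (is.na(post_left)) {
      if (rel < config$rel_change_threshold)
        post_left <- config$min_post_steps
    } else {
      post_left <- post_left - 1L
    }
    if (!is.na(post_left)) window <- c(window, list(theta))
    if (!is.na(post_left) && post_left <= 0L) {
      converged <- TRUE
      break
    }
  }
  if (converged && length(window)) {
    W <- do.call(rbind, window)
    W <- W[seq(max(1, nrow(W) - config$min_post_steps + 1), nrow(W)), ,
           drop = FALSE]
    theta <- clamp(colMeans(W))
  }
  # SEs from the inverse AI at the final parameter values: the AI matrix
  # approximates the observed information of the (doubled) objective
  st <- reml_state(B, y, X, tau2 = theta[["tau2"]],
                   sigma_e2 = theta[["sigma_e2"]], config = config,
                   grm_factors = grm_factors)
  AI_final <- average_information(st)
  se <- tryCatch(unname(sqrt(diag(2 * solve(AI_final)))),
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(
    tau2 = unname(theta[["tau2"]]), sigma_e2 = unname(theta[["sigma_e2"]]),
    se = c(sigma_e2 = se[1], tau2 = se[2]),
    converged = converged, n_iter = n_iter,
    history = do.call(rbind, history[seq_len(n_iter)]),
    he_init = init, B = B, grm_scale = grm_scale,
    y = y, X = X, config = config, final_state = st),
    class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("ARG-LMM REML fit:\n")
  cat(sprintf("  tau2     = %.6g (SE %.3g)\n", x$tau2, x$se[["tau2"]]))
  cat(sprintf("  sigma_e2 = %.6g (SE %.3g)\n", x$sigma_e2,
              x$se[["sigma_e2"]]))
  cat(sprintf("  %s after %d iterations\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Dense spectral-rotation REML (oracle)
#'
#' Deterministic REML for a dense GRM: after eigendecomposing \eqn{B} and
#' rotating \eqn{y} and \eqn{X} by the eigenvectors, the restricted
#' likelihood factorizes over independent Gaussian coordinates and is
#' maximized over \eqn{(\tau^2, \sigma_\epsilon^2)} by bounded 2-D
#' quasi-Newton search (multi-started).  Serves as the oracle for
#' [fit_reml()] at small N.
#'
#' @param B dense symmetric positive-semidefinite GRM.
#' @param y phenotype vector.
#' @param X covariate matrix including intercept.
#' @return list with `tau2`, `sigma_e2`, `objective` (the minimized
#'   value), and `objective_fn` (the function of `c(tau2, sigma_e2)`).
#' @export
dense_spectral_reml <- function(B, y, X) {
  B <- as.matrix(B)
  y <- as.numeric(y)
  X <- as.matrix(X)
  N <- length(y)
  K <- ncol(X)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values)))
    stop("B is not positive semidefinite")
  lam <- pmax(eg$values, 0)
  yr <- drop(crossprod(eg$vectors, y))
  Xr <- crossprod(eg$vectors, X)
  obj <- function(par) {
    tau2 <- par[1]; s2 <- par[2]
    d <- tau2 * lam + s2
    if (any(d <= 0)) return(Inf)
    XtViX <- crossprod(Xr, Xr / d)
    XtViy <- crossprod(Xr, yr / d)
    ld2 <- determinant(XtViX, logarithm = TRUE)$modulus
    yPy <- sum(yr^2 / d) - drop(crossprod(XtViy, solve(XtViX, XtViy)))
    (N - K) * log(2 * pi) + sum(log(d)) + as.numeric(ld2) + yPy
  }
  vy <- var(y)
  lam_bar <- mean(lam)
  if (lam_bar <= 0) lam_bar <- 1       # B = 0: tau2 is unidentifiable
  starts <- list(c(vy / (2 * lam_bar), vy / 2),
                 c(vy / (10 * lam_bar), 0.9 * vy),
                 c(2 * vy / lam_bar, 0.1 * vy))
  lower <- c(1e-10 * vy / lam_bar, 1e-10 * vy)
  best <- NULL
  for (s in starts) {
    fit <- optim(pmax(s, lower), obj, method = "L-BFGS-B", lower = lower,
                 control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(tau2 = best$par[1], sigma_e2 = best$par[2], objective = best$value,
       objective_fn = obj)
}

#' Additive genetic variance from a fitted model
#'
#' Estimates the realized additive genetic variance
#' \eqn{V_G = \frac1N \sum_i (g_i - \bar g)^2} of the sample as
#' \eqn{\hat\tau^2 \, tr(\tilde B)/N}, where \eqn{\tilde B} is the
#' centered GRM, with standard error
#' \eqn{\hat\tau^2\sqrt{2\,tr(\tilde B^2)}/N}, the sampling spread of
#' \eqn{V_G} over realizations of the generative model (the variance of a
#' Gaussian quadratic form).  Both traces are estimated by [xtrace()] on
#' the centered operator.
#'
#' @param fit a [fit_reml()] result.
#' @param arg optional [arg_data()]; defaults to the operator stored in
#'   the fit.
#' @param n_vectors,seed trace-estimation controls.
#' @return list with `vg`, `se`.
#' @export
estimate_vg <- function(fit, arg = NULL, n_vectors = 50L, seed = NULL) {
  B <- if (is.null(arg)) fit$B else
    branch_grm_operator(arg, scale = fit$grm_scale)
  N <- B$dim
  center <- function(x) sweep(x, 2, colMeans(x))
  Bc <- linop(N, function(x) center(linop_apply(B, center(as.matrix(x)))))
  seeds <- derive_seeds(seed, 2)
  tr_bc <- xtrace(Bc, n_vectors, seeds[[1]])$value
  Bc2 <- linop(N, function(x) linop_apply(Bc, linop_apply(Bc, x)))
  tr_bc2 <- xtrace(Bc2, n_vectors, seeds[[2]])$value
  list(vg = fit$tau2 * tr_bc / N,
       se = fit$tau2 * sqrt(2 * max(tr_bc2, 0)) / N)
}
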