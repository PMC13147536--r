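# Shared small fixture: a simulated ARG with phenotypes from the
# generative model, plus its dense GRM.
reml_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      arg <- cached_arg(100, 1e5, seed = 91)
      scale <- 4 * total_root_area(arg)
      sim <- simulate_phenotypes(arg, phenotype_spec(1, 1), seed = 13)
      cache <<- list(arg = arg, scale = scale, y = sim$y,
                     B = dense_branch_grm(arg) / scale,
                     X = matrix(1, n_individuals(arg), 1),
                     Bop = branch_grm_operator(arg, scale = scale))
    }
    cache
  }
})

test_that("project_P reduces to centering for V = I and annihilates X", {
  fx <- reml_fixture()
  st <- reml_state(fx$Bop, fx$y, fx$X, tau2 = 1e-12, sigma_e2 = 1)
  expect_equal(project_P(st, fx$y), fx$y - mean(fx$y), tolerance = 1e-6)
  st2 <- reml_state(fx$Bop, fx$y, fx$X, tau2 = 0.7, sigma_e2 = 1.1)
  expect_lt(max(abs(project_P(st2, fx$X))), 1e-6 * max(abs(fx$y)))
  # dense equivalence
  Pd <- dense_P(fx$B, fx$X, 0.7, 1.1)
  v <- rnorm(length(fx$y))
  expect_equal(project_P(st2, v), drop(Pd %*% v), tolerance = 1e-4)
})

test_that("GLS coefficients reduce to OLS under V = I", {
  fx <- reml_fixture()
  N <- length(fx$y)
  X <- cbind(1, rnorm(N))
  Iop <- linop(N, function(v) 0 * v)
  st <- reml_state(Iop, fx$y, X, tau2 = 0, sigma_e2 = 1)
  expect_equal(gls_coefficients(st), drop(qr.coef(qr(X), fx$y)),
               tolerance = 1e-5, ignore_attr = TRUE)
  st1 <- reml_state(Iop, fx$y, matrix(1, N, 1), tau2 = 0, sigma_e2 = 1)
  expect_equal(unname(gls_coefficients(st1)), mean(fx$y), tolerance = 1e-6)
})

test_that("the gradient matches the dense formula with exact traces", {
  fx <- reml_fixture()
  N <- length(fx$y)
  st <- reml_state(fx$Bop, fx$y, fx$X, tau2 = 0.5, sigma_e2 = 1.2,
                   config = reml_config(cg_tol = 1e-8))
  Vd <- 0.5 * fx$B + 1.2 * diag(N)
  Vi <- solve(Vd)
  Pd <- dense_P(fx$B, fx$X, 0.5, 1.2)
  Py <- drop(Pd %*% fx$y)
  g_dense <- c(sum(diag(Pd)) - sum(Py^2),
               sum(diag(Pd %*% fx$B)) - sum(Py * (fx$B %*% Py)))
  g <- reml_gradient(st, tr_vinv = sum(diag(Vi)),
                     tr_vinv_b = sum(Vi * fx$B))
  expect_equal(unname(g), g_dense, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the null-model score in sigma_e2 vanishes at the sample variance", {
  # tau2 ~ 0, X = intercept: gradient_sigma = (N-1)(1 - s2/sig2)/sig2
  fx <- reml_fixture()
  N <- length(fx$y)
  s2 <- sum((fx$y - mean(fx$y))^2) / (N - 1)
  for (sig2 in c(0.5 * s2, s2, 2 * s2)) {
    st <- reml_state(fx$Bop, fx$y, fx$X, tau2 = 1e-14, sigma_e2 = sig2,
                     config = reml_config(cg_tol = 1e-10))
    g <- reml_gradient(st, tr_vinv = N / sig2,
                       tr_vinv_b = sum(diag(fx$B)) / sig2)
    expect_equal(g[["sigma_e2"]], (N - 1) * (1 - s2 / sig2) / sig2,
                 tolerance = 1e-4)
  }
})

test_that("the AI matrix is symmetric PSD and averages Hessian and Fisher", {
  fx <- reml_fixture()
  tau2 <- 0.6; sig2 <- 1.3
  st <- reml_state(fx$Bop, fx$y, fx$X, tau2 = tau2, sigma_e2 = sig2,
                   config = reml_config(cg_tol = 1e-9))
  AI <- average_information(st)
  expect_identical(AI[1, 2], AI[2, 1])
  expect_true(all(eigen(AI, only.values = TRUE)$values > -1e-8 * AI[1, 1]))
  # y = 0 gives the zero matrix
  st0 <- reml_state(fx$Bop, c(1e-8, rep(0, length(fx$y) - 1)),
                    fx$X, tau2 = 0.6, sigma_e2 = 1.3)
  expect_lt(max(abs(average_information(st0))), 1e-10)
  # dense reference: AI = (numerical Hessian + Fisher) / 2 of the
  # (doubled, negated-log) restricted likelihood
  obj <- dense_spectral_reml(fx$B, fx$y, fx$X)$objective_fn
  h <- 1e-3
  num_hess <- matrix(0, 2, 2)
  base_par <- c(tau2, sig2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h; ej[j] <- h
    num_hess[i, j] <- (obj(base_par + ei + ej) - obj(base_par + ei) -
                         obj(base_par + ej) + obj(base_par)) / h^2
  }
  Pd <- dense_P(fx$B, fx$X, tau2, sig2)
  Vdots <- list(tau2 = fx$B, sigma_e2 = diag(length(fx$y)))
  fisher <- outer(1:2, 1:2, Vectorize(function(i, j)
    sum(diag(Pd %*% Vdots[[i]] %*% Pd %*% Vdots[[j]]))))
  ref <- (num_hess + fisher) / 2        # order (tau2, sigma_e2)
  expect_equal(AI[c("tau2", "sigma_e2"), c("tau2", "sigma_e2")], ref,
               tolerance = 5e-2, ignore_attr = TRUE)
})

test_that("Haseman-Elston matches the dense system with exact traces", {
  fx <- reml_fixture()
  N <- length(fx$y)
  expect_equal(he_initialize(fx$Bop, rep(0, N), fx$X, seed = 1,
                             tr_b = sum(diag(fx$B)),
                             tr_b2 = sum(fx$B^2)),
               list(tau2 = 0, sigma_e2 = 0))
  r <- fx$y - mean(fx$y)
  M <- matrix(c(sum(fx$B^2), sum(diag(fx$B)), sum(diag(fx$B)), N), 2)
  sol <- solve(M, c(drop(t(r) %*% fx$B %*% r), sum(r^2)))
  he <- he_initialize(fx$Bop, fx$y, fx$X, seed = 1,
                      tr_b = sum(diag(fx$B)), tr_b2 = sum(fx$B^2))
  expect_equal(c(he$tau2, he$sigma_e2), sol, tolerance = 1e-8)
  # B proportional to I makes the system singular
  Iop <- linop(N, function(v) 2 * v)
  expect_error(he_initialize(Iop, fx$y, fx$X, tr_b = 2 * N, tr_b2 = 4 * N),
               "singular")
})

test_that("dense spectral REML handles the null model and is optimal", {
  fx <- reml_fixture()
  N <- length(fx$y)
  X <- cbind(1, rnorm(N))
  d0 <- dense_spectral_reml(matrix(0, N, N), fx$y, X)
  expect_equal(d0$sigma_e2, sum(qr.resid(qr(X), fx$y)^2) / (N - 2),
               tolerance = 1e-4)
  dd <- dense_spectral_reml(fx$B, fx$y, fx$X)
  # no grid point near the optimum improves on the returned objective
  grid <- expand.grid(tau2 = dd$tau2 * seq(0.5, 1.5, length.out = 10),
                      sigma_e2 = dd$sigma_e2 * seq(0.5, 1.5, length.out = 10))
  vals <- apply(grid, 1, dd$objective_fn)
  expect_lte(dd$objective, min(vals) + 1e-6)
})

test_that("fit_reml recovers a pure-noise model", {
  arg <- cached_arg(300, 5e5, seed = 93)
  N <- n_individuals(arg)
  scale <- 4 * total_root_area(arg)
  y0 <- arglmm:::with_seed(5, rnorm(N, 0, sqrt(2)))
  fit <- fit_reml(arg, y0, config = reml_config(seed = 3, max_iter = 60),
                  grm_scale = scale)
  expect_true(fit$converged)
  expect_lt(fit$tau2, 0.1)
  expect_equal(fit$sigma_e2, var(y0), tolerance = 0.15)
  expect_error(fit_reml(arg, rep(1, N), grm_scale = scale), "constant")
})

test_that("fit history records the iterates averaged into the estimate", {
  fx <- reml_fixture()
  fit <- fit_reml(fx$arg, fx$y, config = reml_config(seed = 17,
                                                     max_iter = 60),
                  grm_scale = fx$scale)
  expect_true(fit$converged)
  h <- fit$history
  expect_equal(nrow(h), fit$n_iter)
  k <- fit$config$min_post_steps
  expect_equal(mean(h$tau2[seq(fit$n_iter - k + 1, fit$n_iter)]), fit$tau2,
               tolerance = 1e-12)
  expect_true(all(h$ai_ss >= 0 & h$ai_tt >= 0))
})
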