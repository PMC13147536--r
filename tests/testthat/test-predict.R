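# A fitted-model stub with prescribed components, for prediction tests
# that do not depend on the estimation path.
stub_fit <- function(B, tau2, sigma_e2, grm_scale = 1) {
  structure(list(tau2 = tau2, sigma_e2 = sigma_e2, converged = TRUE,
                 grm_scale = grm_scale, B = B,
                 config = reml_config(seed = 1)),
            class = "reml_fit")
}

pred_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      arg <- cached_arg(80, 1e5, seed = 101)
      scale <- 4 * total_root_area(arg)
      sim <- simulate_phenotypes(arg, phenotype_spec(1, 1), seed = 23)
      cache <<- list(arg = arg, scale = scale, y = sim$y, g = sim$g,
                     B = dense_branch_grm(arg) / scale,
                     N = n_individuals(arg))
    }
    cache
  }
})

test_that("BLUPs vanish when tau2-hat is zero", {
  fx <- pred_fixture()
  fit <- stub_fit(dense_operator(fx$B), tau2 = 0, sigma_e2 = 1.3)
  bl <- predict_blup(NULL, fit, fx$y[1:40], obs_index = 1:40,
                     target_index = 41:60)
  expect_equal(bl$predicted, rep(0, 20))
})

test_that("with no noise and targets = observed, BLUPs interpolate", {
  fx <- pred_fixture()
  fit <- stub_fit(dense_operator(fx$B), tau2 = 0.8, sigma_e2 = 0)
  obs <- seq_len(fx$N)
  bl <- predict_blup(NULL, fit, fx$y, obs_index = obs, target_index = obs)
  bhat <- bl$coefficients
  expect_equal(bl$predicted, fx$y - bhat, tolerance = 1e-4)
})

test_that("implicit BLUP matches the dense conditional mean and variance", {
  fx <- pred_fixture()
  fit <- fit_reml(fx$arg, fx$y,
                  config = reml_config(seed = 31, max_iter = 60,
                                       cg_tol = 1e-9),
                  grm_scale = fx$scale)
  obs <- sort(arglmm:::with_seed(1, sample(fx$N, fx$N / 2)))
  tgt <- setdiff(seq_len(fx$N), obs)
  bl <- predict_blup(fx$arg, fit, fx$y[obs], obs_index = obs,
                     target_index = tgt, with_variance = TRUE)
  V_oo <- fit$tau2 * fx$B[obs, obs] + fit$sigma_e2 * diag(length(obs))
  Xo <- matrix(1, length(obs), 1)
  bhat <- solve(t(Xo) %*% solve(V_oo, Xo), t(Xo) %*% solve(V_oo, fx$y[obs]))
  r <- solve(V_oo, fx$y[obs] - drop(Xo %*% bhat))
  g_dense <- fit$tau2 * fx$B[tgt, obs] %*% r
  expect_lt(max(abs(bl$predicted - g_dense)) / max(abs(g_dense)), 1e-6)
  cv_dense <- fit$tau2 * fx$B[tgt, tgt] -
    fit$tau2^2 * fx$B[tgt, obs] %*% solve(V_oo, fx$B[obs, tgt])
  expect_lt(max(abs(bl$conditional_variance - cv_dense)) /
              max(abs(cv_dense)), 1e-5)
  # conditioning cannot inflate variance beyond the prior
  expect_true(all(diag(bl$conditional_variance) <=
                    fit$tau2 * diag(fx$B)[tgt] + 1e-8))
  expect_error(predict_blup(fx$arg, fit, fx$y[obs], obs_index = integer(0),
                            target_index = tgt), "empty")
})

test_that("predicted magnitude shrinks as noise variance grows", {
  fx <- pred_fixture()
  obs <- 1:40; tgt <- 41:80
  norms <- vapply(c(0.2, 0.5, 1, 2, 5), function(s2) {
    fit <- stub_fit(dense_operator(fx$B), tau2 = 1, sigma_e2 = s2)
    sqrt(sum(predict_blup(NULL, fit, fx$y[obs], obs_index = obs,
                          target_index = tgt)$predicted^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("windowed linear combinations sum to the genome-wide BLUP", {
  fx <- pred_fixture()
  arg <- fx$arg
  fit <- stub_fit(NULL, tau2 = 0.9, sigma_e2 = 1.1, grm_scale = fx$scale)
  fit$B <- branch_grm_operator(arg, scale = fx$scale)
  obs <- 1:40; tgt <- 41:80
  mid <- arg$sequence_length / 2
  clip <- function(lo, hi) {
    e <- arg$edges
    e$left <- pmax(e$left, lo); e$right <- pmin(e$right, hi)
    e <- e[e$left < e$right, ]
    arg_data(arg$node_time, arg$node_is_sample, e, arg$sequence_length,
             arg$individuals)
  }
  B1 <- dense_branch_grm(clip(0, mid)) / fx$scale
  B2 <- dense_branch_grm(clip(mid, arg$sequence_length)) / fx$scale
  expect_equal(B1 + B2, fx$B, tolerance = 1e-10)   # additivity over windows
  cc <- function(Bw) function(v) fit$tau2 * drop(Bw[tgt, obs] %*% v)
  p1 <- predict_linear_combination(arg, fit, fx$y[obs], obs_index = obs,
                                   cross_cov = cc(B1))
  p2 <- predict_linear_combination(arg, fit, fx$y[obs], obs_index = obs,
                                   cross_cov = cc(B2))
  full <- predict_blup(arg, fit, fx$y[obs], obs_index = obs,
                       target_index = tgt)
  expect_equal(p1 + p2, full$predicted, tolerance = 1e-5)
  zero <- predict_linear_combination(arg, fit, fx$y[obs], obs_index = obs,
                                     cross_cov = function(v) 0 * v[1:5])
  expect_equal(zero, rep(0, 5))
})

test_that("a non-converged fit warns but still predicts", {
  fx <- pred_fixture()
  fit <- stub_fit(dense_operator(fx$B), tau2 = 0.5, sigma_e2 = 1)
  fit$converged <- FALSE
  expect_warning(
    bl <- predict_blup(NULL, fit, fx$y[1:40], obs_index = 1:40,
                       target_index = 41:50),
    "non-converged")
  expect_length(bl$predicted, 10)
})
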