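test_that("coalescent simulation has the contracted structure", {
  arg <- simulate_arg(sim_params(n_diploids = 2, sequence_length = 1e4,
                                 recombination_rate = 0, seed = 2))
  expect_equal(length(arg$samples), 4)
  expect_equal(n_individuals(arg), 2)
  expect_equal(n_local_trees(arg), 1)
  expect_true(all(lengths(arg$individuals) == 2))

  a1 <- cached_arg(20, 1e5, seed = 111)
  a2 <- simulate_arg(sim_params(n_diploids = 20, sequence_length = 1e5,
                                demography = "constant", Ne = 5000,
                                seed = 111))
  expect_identical(a1$edges, a2$edges)      # same seed, same tables
  expect_gt(n_local_trees(a1), 1)           # recombination produces trees
})

test_that("phenotype simulation matches its generative contract", {
  arg <- cached_arg(150, 1e5, seed = 121, Ne = 1e5, demography = "decline")
  # tau2 = 0: pure noise at the stated variance
  sim0 <- simulate_phenotypes(arg, phenotype_spec(0, 1.5), seed = 1)
  expect_equal(sim0$g, rep(0, 150))
  expect_equal(var(sim0$y), 1.5, tolerance = 0.35)
  # comparable genetic and environmental variance at tau2 = sigma2 = 1
  ratios <- vapply(1:6, function(s) {
    sim <- simulate_phenotypes(arg, phenotype_spec(1, 1), seed = s)
    var(sim$g) / 1
  }, numeric(1))
  expect_true(all(ratios > 0.25 & ratios < 4))
  # reproducible under a fixed seed
  s1 <- simulate_phenotypes(arg, phenotype_spec(1, 1), seed = 9)
  s2 <- simulate_phenotypes(arg, phenotype_spec(1, 1), seed = 9)
  expect_identical(s1$y, s2$y)
  expect_identical(s1$g, s2$g)
  expect_equal(s1$grm_scale, 4 * total_root_area(arg))
})

test_that("replicate phenotypes obey the ARG-LMM covariance", {
  arg <- cached_arg(8, 3e4, seed = 61)
  scale2 <- 4 * total_root_area(arg)
  Bs <- dense_branch_grm(arg) / scale2
  tau2 <- 1.2; s2 <- 0.8
  R <- 800
  Y <- vapply(seq_len(R), function(i)
    simulate_phenotypes(arg, phenotype_spec(tau2, s2), seed = i)$y,
    numeric(8))
  emp <- tcrossprod(Y) / R
  target <- tau2 * Bs + s2 * diag(8)
  se <- sqrt((diag(target) %o% diag(target) + target^2) / R)
  expect_true(all(abs(emp - target) < 4.5 * se))
})

test_that("the SNP GRM follows the printed formula and filters variants", {
  G <- rbind(c(0, 2), c(2, 2))              # variant 2 is monomorphic
  grm <- snp_grm(G, maf_min = 0.005)
  expect_equal(attr(grm, "n_variants"), 1)
  expect_equal(unclass(grm), matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)
  expect_error(snp_grm(cbind(c(0, 0), c(2, 2))), "MAF")
  # centering identity with sample frequencies
  set.seed(3)
  G2 <- matrix(rbinom(20 * 30, 2, 0.4), 20)
  grm2 <- snp_grm(G2, maf_min = 0.01)
  expect_lt(max(abs(grm2 %*% rep(1, 20))), 1e-10 * max(abs(grm2)))
})

test_that("Monte-Carlo GRM products are unbiased for mu * Bw", {
  arg <- cached_arg(10, 4e4, seed = 41)
  N <- n_individuals(arg)
  w <- arglmm:::with_seed(2, rnorm(N))
  expect_equal(montecarlo_grm_matvec(arg, 0, w, seed = 1), numeric(N))
  mu <- 1e-7
  exact <- mu * grm_matvec(arg, w)
  R <- 150
  draws <- vapply(seq_len(R),
                  function(s) montecarlo_grm_matvec(arg, mu, w, seed = s),
                  numeric(N))
  m <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(R)
  expect_true(all(abs(m - exact) < 4.5 * pmax(se, 1e-12)))
})

test_that("structured fixtures reshape the GRM spectrum", {
  pan <- structured_fixture(1, n_diploids = 30, Ne = 4000,
                            sequence_length = 5e4, seed = 131)
  str8 <- structured_fixture(8, migration = 1e-4, n_diploids = 30,
                             Ne = 4000, sequence_length = 5e4, seed = 131)
  ratio <- function(a) {
    B <- dense_branch_grm(a, centered = TRUE)
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    max(ev) / sum(pmax(ev, 0))
  }
  # low-migration demes concentrate relatedness into deme-contrast modes:
  # the top eigenvalue carries a larger share of the trace than under
  # panmixia at equal N
  expect_gt(ratio(str8), ratio(pan))
  # end-to-end smoke: fit + BLUP run on the structured fixture
  sim <- simulate_phenotypes(str8, phenotype_spec(1, 1), seed = 3)
  fit <- fit_reml(str8, sim$y,
                  config = reml_config(seed = 5, max_iter = 40),
                  grm_scale = sim$grm_scale)
  bl <- suppressWarnings(predict_blup(str8, fit, sim$y[1:15],
                                      obs_index = 1:15,
                                      target_index = 16:30))
  expect_length(bl$predicted, 15)
  expect_true(all(is.finite(bl$predicted)))
})

test_that("mutation-effect phenotypes drive consistent fits", {
  arg <- cached_arg(200, 3e5, seed = 141, mutation_rate = 1e-8)
  expect_gt(nrow(arg$mutations), 50)
  simg <- simulate_phenotypes(arg, phenotype_spec(1, 1, mode = "subedge"),
                              seed = 11)
  simm <- simulate_phenotypes(
    arg, phenotype_spec(1, 1, mode = "mutation", causal_fraction = 0.1),
    seed = 11)
  expect_false(identical(simg$g, simm$g))
  fit_g <- fit_reml(arg, simg$y, config = reml_config(seed = 1,
                                                      max_iter = 50),
                    grm_scale = simg$grm_scale)
  fit_m <- fit_reml(arg, simm$y, config = reml_config(seed = 1,
                                                      max_iter = 50),
                    grm_scale = simm$grm_scale)
  # both modes admit a genetic component of the same order; discrete
  # mutation effects do not break the estimator
  expect_true(fit_m$sigma_e2 > 0.5 && fit_m$sigma_e2 < 2)
  expect_true(is.finite(fit_m$tau2) && fit_m$tau2 >= 0)
  expect_true(fit_g$converged && fit_m$converged)
})
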