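#' Coalescent simulation parameters
#'
#' Defaults reproduce the evaluation conditions of the simulation harness:
#' a panmictic population of 100,000 diploids today that declines backward
#' in time at a continuous rate of 1% per generation, recombination rate
#' \eqn{10^{-8}} per bp per generation, and a 1 Mbp genome.
#'
#' @param n_diploids number of sampled diploid individuals.
#' @param sequence_length genome length, bp.
#' @param recombination_rate per bp per generation.
#' @param demography `"decline"` (exponential decline backward in time at
#'   `growth_rate`) or `"constant"`.
#' @param Ne present-day population size (diploids).
#' @param growth_rate continuous decline rate per generation (backward).
#' @param mutation_rate per bp per generation; 0 skips mutations.
#' @param n_demes number of demes in a linear stepping-stone (1 =
#'   panmictic); total size `Ne` is split evenly.
#' @param migration_rate per-generation migration rate between adjacent
#'   demes.
#' @param seed integer seed for the simulator.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_diploids, sequence_length = 1e6,
                       recombination_rate = 1e-8,
                       demography = c("decline", "constant"), Ne = 1e5,
                       growth_rate = 0.01, mutation_rate = 0,
                       n_demes = 1L, migration_rate = 0, seed = 1L) {
  demography <- match.arg(demography)
  stopifnot(n_diploids >= 2, sequence_length > 0, recombination_rate >= 0,
            mutation_rate >= 0, Ne > 0, n_demes >= 1, migration_rate >= 0)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a coalescent ARG
#'
#' Runs msprime (through the bundled Python helper) under the demography
#' in `params` and returns the resulting tree sequence as an
#' [arg_data()] object with `2 * n_diploids` haplotypes grouped into
#' diploid individuals.
#'
#' @param params a [sim_params()] object.
#' @param python Python interpreter with msprime installed.
#' @return an [arg_data()] object.
#' @export
simulate_arg <- function(params, python = Sys.which("python")) {
  stopifnot(inherits(params, "sim_params"))
  out <- tempfile("sim_arg_")
  on.exit(unlink(out, recursive = TRUE))
  run_python_tool("simulate", c(
    "--n-diploids", params$n_diploids,
    "--sequence-length", format(params$sequence_length, scientific = FALSE),
    "--recombination-rate", params$recombination_rate,
    "--demography", params$demography,
    "--ne", format(params$Ne, scientific = FALSE),
    "--growth-rate", params$growth_rate,
    "--mutation-rate", params$mutation_rate,
    "--n-demes", params$n_demes,
    "--migration-rate", params$migration_rate,
    "--seed", params$seed,
    "--out", out), python)
  read_arg_tables(out)
}

#' Phenotype simulation specification
#'
#' @param tau2 genetic variance component (after scaling; see Details).
#' @param sigma_e2 environmental variance.
#' @param mode `"subedge"` draws Gaussian sub-edge effects from the
#'   generative ARG model ([simulate_genetic_values()]); `"mutation"`
#'   assigns standard-normal effects to a fraction of the simulated
#'   mutations and sums dosages.
#' @param causal_fraction fraction of mutations that are causal
#'   (`"mutation"` mode).
#' @details Genetic values are divided by the scaling constant
#'   \eqn{\sqrt{4 \sum_T s_T t_{root,T}}} so that genetic and
#'   environmental variances are comparable; the phenotype is
#'   \eqn{y = \tau g_{scaled} + \epsilon}.  Under this scaling the model
#'   GRM is `B / (4 * total_root_area(arg))`, the value to pass as
#'   `grm_scale` to [fit_reml()].
#' @export
phenotype_spec <- function(tau2, sigma_e2, mode = c("subedge", "mutation"),
                           causal_fraction = 0.01) {
  mode <- match.arg(mode)
  stopifnot(tau2 >= 0, sigma_e2 >= 0,
            causal_fraction > 0, causal_fraction <= 1)
  structure(list(tau2 = tau2, sigma_e2 = sigma_e2, mode = mode,
                 causal_fraction = causal_fraction),
            class = "phenotype_spec")
}

#' Simulate phenotypes under the ARG-LMM
#'
#' @param arg an [arg_data()] object (with a mutation table when
#'   `spec$mode == "mutation"`).
#' @param spec a [phenotype_spec()].
#' @param seed integer seed.
#' @return list with `y` (phenotypes), `g` (the genetic component of
#'   `y`), `scaling` (the constant the raw genetic values were divided
#'   by), `grm_scale` (its square: the GRM divisor matching the
#'   phenotype scale), and the generating components.
#' @export
simulate_phenotypes <- function(arg, spec, seed = NULL) {
  stopifnot(inherits(spec, "phenotype_spec"))
  N <- n_individuals(arg)
  area <- total_root_area(arg)
  if (area <= 0) stop("ARG has zero total root area; cannot scale")
  scaling <- sqrt(4 * area)
  seeds <- derive_seeds(seed, 3)
  if (spec$mode == "subedge") {
    g_raw <- simulate_genetic_values(arg, tau2 = spec$tau2, seed = seeds[[1]])
    g <- g_raw / scaling
  } else {
    m <- arg$mutations
    if (is.null(m))
      stop("mutation-effect mode requires an ARG simulated with ",
           "mutation_rate > 0")
    g <- with_seed(seeds[[1]], {
      causal <- runif(nrow(m)) < spec$causal_fraction
      beta <- ifelse(causal, rnorm(nrow(m)), 0)
      mutation_genetic_values(arg, beta)
    })
    g <- sqrt(spec$tau2) * g / scaling
  }
  eps <- with_seed(seeds[[2]], rnorm(N, 0, sqrt(spec$sigma_e2)))
  list(y = g + eps, g = g, scaling = scaling, grm_scale = scaling^2,
       tau2 = spec$tau2, sigma_e2 = spec$sigma_e2, mode = spec$mode)
}

#' SNP genotype GRM
#'
#' The standard frequency-standardized genotype GRM
#' \deqn{GRM_{ij} = \frac1M \sum_k
#'   \frac{(x_{ik} - 2 p_k)(x_{jk} - 2 p_k)}{2 p_k (1 - p_k)}}
#' over the \eqn{M} variants passing the minor-allele-frequency filter;
#' monomorphic variants are always excluded.
#'
#' @param genotypes individuals x variants dosage matrix (entries 0/1/2).
#' @param maf_min minimum minor allele frequency (default 0.005).
#' @return symmetric N x N matrix; attribute `"n_variants"` gives M.
#' @export
snp_grm <- function(genotypes, maf_min = 0.005) {
  G <- as.matrix(genotypes)
  p <- colMeans(G) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min & p > 0 & p < 1
  if (!any(keep))
    stop("no variants remain after the MAF filter")
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  Xs <- sweep(G, 2, 2 * p)
  Xs <- sweep(Xs, 2, sqrt(2 * p * (1 - p)), "/")
  M <- ncol(Xs)
  out <- tcrossprod(Xs) / M
  attr(out, "n_variants") <- M
  out
}

#' Monte-Carlo branch-GRM-vector product
#'
#' Approximates \eqn{\mu B w} by placing Poisson(\eqn{\mu A_e}) mutations
#' on each sub-edge and forming the unnormalized genotype cross-product
#' (no frequency weighting, no centering) with `w`.  The expectation over
#' seeds is exactly \eqn{\mu} times the exact product; accuracy improves
#' with \eqn{\mu}.  Oracle-scale: materializes the sub-edge decomposition.
#'
#' @param arg an [arg_data()] object (small).
#' @param mu Monte-Carlo mutation rate per bp per generation.
#' @param w weight vector over individuals.
#' @param seed integer seed.
#' @return vector over individuals.
#' @export
montecarlo_grm_matvec <- function(arg, mu, w, seed = NULL) {
  stopifnot(mu >= 0)
  N <- n_individuals(arg)
  stopifnot(length(w) == N)
  if (mu == 0) return(numeric(N))
  se <- subedge_decompose(arg)
  sets <- attr(se, "samples")
  map <- sample_individual_map(arg)
  counts <- with_seed(seed, rpois(nrow(se), mu * se$area))
  v <- numeric(N)
  for (i in which(counts > 0)) {
    z <- numeric(N)
    tab <- table(map[match(sets[[i]], arg$samples)])
    z[as.integer(names(tab))] <- as.integer(tab)
    v <- v + counts[i] * z * sum(z * w)
  }
  v
}

#' Structured-population test fixture
#'
#' A reduced stand-in for spatially structured designs: a linear
#' stepping-stone coalescent ARG whose GRM spectrum decays more slowly
#' than the panmictic fixture at equal sample size (strong structure
#' spreads relatedness across many eigenvectors).  With one deme it
#' reduces to the panmictic constant-size fixture.
#'
#' @param n_demes number of demes.
#' @param migration per-generation migration rate between adjacent demes.
#' @param n_diploids total diploid sample size.
#' @param Ne total population size across demes.
#' @param sequence_length,recombination_rate,seed passed through.
#' @return an [arg_data()] object.
#' @export
structured_fixture <- function(n_demes, migration = 1e-3, n_diploids = 40,
                               Ne = 1e4, sequence_length = 1e5,
                               recombination_rate = 1e-8, seed = 1L) {
  simulate_arg(sim_params(
    n_diploids = n_diploids, sequence_length = sequence_length,
    recombination_rate = recombination_rate, demography = "constant",
    Ne = Ne, n_demes = n_demes, migration_rate = migration, seed = seed))
}

#' @importFrom stats rpois runif
NULL
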