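# Hand-built ARGs and cached simulated fixtures shared across test files.

# Two haploid samples joined at a root at time t over a genome of length L.
two_haploid_arg <- function(t = 100, L = 1000) {
  arg_data(
    node_time = c(0, 0, t),
    node_is_sample = c(TRUE, TRUE, FALSE),
    edges = data.frame(left = 0, right = L, parent = 2, child = 0:1),
    sequence_length = L)
}

# Two local trees; the edge above node 3 persists across both trees but a
# recombination below it swaps which sample subtends it, so it splits into
# two sub-edges.
two_tree_arg <- function(L = 1000) {
  arg_data(
    node_time = c(0, 0, 0, 1, 2),
    node_is_sample = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    edges = data.frame(
      left   = c(0, 0,   L / 2, 0,   L / 2, 0),
      right  = c(L, L / 2, L,   L / 2, L,   L),
      parent = c(3, 3,   3,    4,   4,    4),
      child  = c(0, 1,   2,    2,   1,    3)),
    sequence_length = L)
}

# Cache msprime simulations so repeated calls across tests are free.
.arg_cache <- new.env(parent = emptyenv())
cached_arg <- function(n_diploids, sequence_length, seed, Ne = 5000,
                       demography = "constant", mutation_rate = 0,
                       n_demes = 1L, migration_rate = 0) {
  key <- paste(n_diploids, sequence_length, seed, Ne, demography,
               mutation_rate, n_demes, migration_rate, sep = "_")
  if (is.null(.arg_cache[[key]]))
    .arg_cache[[key]] <- simulate_arg(sim_params(
      n_diploids = n_diploids, sequence_length = sequence_length,
      recombination_rate = 1e-8, demography = demography, Ne = Ne,
      mutation_rate = mutation_rate, n_demes = n_demes,
      migration_rate = migration_rate, seed = seed))
  .arg_cache[[key]]
}

# Dense GRM reconstructed from the explicit sub-edge decomposition
# (independent of the per-tree accumulation in dense_branch_grm).
dense_grm_from_subedges <- function(arg, level = "haplotype") {
  se <- subedge_decompose(arg)
  sets <- attr(se, "samples")
  nh <- length(arg$samples)
  B <- matrix(0, nh, nh)
  for (i in seq_len(nrow(se))) {
    idx <- match(sets[[i]], arg$samples)
    B[idx, idx] <- B[idx, idx] + se$area[i]
  }
  if (level == "individual") {
    map <- arglmm:::sample_individual_map(arg)
    H <- matrix(0, nh, length(arg$individuals))
    H[cbind(seq_len(nh), map)] <- 1
    B <- crossprod(H, B %*% H)
  }
  B
}

# Plain Hutchinson trace estimator (test-only reference for xtrace).
hutchinson_trace <- function(A, n_vectors, seed) {
  om <- arglmm:::with_seed(seed, matrix(rnorm(A$dim * n_vectors), A$dim))
  mean(colSums(om * linop_apply(A, om)))
}

# Dense REML projection matrix for oracle checks.
dense_P <- function(B, X, tau2, sigma_e2) {
  V <- tau2 * B + sigma_e2 * diag(nrow(B))
  Vi <- solve(V)
  Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
}
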