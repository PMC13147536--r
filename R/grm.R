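#' Dense branch GRM (small-sample oracle)
#'
#' Materializes the branch GRM \eqn{B = Z \Sigma_A Z^T} by iterating over
#' local trees.  Exists as an oracle for the implicit product
#' [grm_matvec()]; refuses to run above a guard size.
#'
#' @param arg an [arg_data()] object.
#' @param centered if `TRUE`, return the centered GRM
#'   \eqn{\tilde B = P_N B P_N} with \eqn{P_N = I - \frac1N 1 1^T}.
#' @param level `"individual"` (default) sums haplotype rows/columns per
#'   individual; `"haplotype"` returns the sample-node-level matrix.
#' @param guard refuse to build matrices larger than this.
#' @return a symmetric positive semidefinite matrix.
#' @export
dense_branch_grm <- function(arg, centered = FALSE,
                             level = c("individual", "haplotype"),
                             guard = 2000) {
  level <- match.arg(level)
  n_h <- length(arg$samples)
  n <- if (level == "individual") n_individuals(arg) else n_h
  if (n > guard)
    stop("dense GRM requested for N = ", n, " > guard = ", guard,
         "; use the implicit grm_matvec() instead")
  B <- matrix(0, n_h, n_h)
  for (tr in local_trees(arg)) {
    below <- samples_below(tr$parent, arg$samples)
    span <- tr$right - tr$left
    for (u1 in which(!is.na(tr$edge))) {
      len <- arg$node_time[tr$parent[u1] + 1L] - arg$node_time[u1]
      idx <- match(below[[u1]], arg$samples)
      B[idx, idx] <- B[idx, idx] + span * len
    }
  }
  if (level == "individual") {
    map <- sample_individual_map(arg)
    H <- matrix(0, n_h, n)
    H[cbind(seq_len(n_h), map)] <- 1
    B <- crossprod(H, B %*% H)
  }
  if (centered) {
    B <- sweep(B, 1, rowMeans(B))
    B <- sweep(B, 2, colMeans(B))
  }
  (B + t(B)) / 2
}

#' Implicit branch-GRM-vector product
#'
#' Computes \eqn{B w} (or products with the centered GRM, or with
#' submatrices \eqn{B[rows, cols]}) exactly from the tree sequence tables,
#' without materializing \eqn{B} or its sub-edges.  An up-pass accumulates,
#' per sub-edge, the weighted count of samples below; the area-weighted sums
#' are then pushed back down to the samples.  Both passes are realized in a
#' single incremental sweep over edge insertions and removals along the
#' genome, costing \eqn{O(N + E \log N)}.
#'
#' For diploid (or arbitrary-ploidy) individuals, each individual's weight
#' is replicated to its sample nodes before the up-pass and node results
#' are summed per individual afterwards, realizing the dosage matrix
#' \eqn{Z} with entries \{0, 1, 2\} without forming it.
#'
#' @param arg an [arg_data()] object.
#' @param w numeric vector of length `length(cols)`, or a matrix with that
#'   many rows (columns are independent products).
#' @param centered if `TRUE`, compute \eqn{(P_N B P_N)[rows, cols] \, w}.
#' @param rows,cols 1-based individual index sets (default: all).
#' @return a vector (or matrix) of length `length(rows)`.
#' @export
grm_matvec <- function(arg, w, centered = FALSE, rows = NULL, cols = NULL) {
  N <- n_individuals(arg)
  if (is.null(rows)) rows <- seq_len(N)
  if (is.null(cols)) cols <- seq_len(N)
  if (any(rows < 1 | rows > N) || any(cols < 1 | cols > N))
    stop("row/col index out of range")
  w <- as.matrix(w)
  if (!all(is.finite(w))) stop("w contains non-finite values")
  if (nrow(w) != length(cols))
    stop("length of w (", nrow(w), ") does not match cols (",
         length(cols), ")")
  full <- matrix(0, N, ncol(w))
  full[cols, ] <- w
  if (centered) full <- sweep(full, 2, colMeans(full))
  map <- sample_individual_map(arg)
  W <- full[map, , drop = FALSE]     # scatter to sample nodes
  res <- .cpp_grm_matvec(arg$node_time, arg$edges$left, arg$edges$right,
                         arg$edges$parent, arg$edges$child,
                         arg$sequence_length, arg$samples, W)
  out <- rowsum(res, map)            # gather per individual (sorted by index)
  dimnames(out) <- NULL
  if (centered) out <- sweep(out, 2, colMeans(out))
  out <- out[rows, , drop = FALSE]
  if (ncol(out) == 1) drop(out) else out
}

#' Simulate genetic values from the generative ARG model
#'
#' Draws one independent Gaussian effect per sub-edge with mean 0 and
#' variance \eqn{\tau^2 A_e} (area \eqn{A_e} in bp-generations), and sums
#' effects of all sub-edges ancestral to each sample; individual values sum
#' their haplotypes.  The resulting vector \eqn{g = Z u} has covariance
#' \eqn{\tau^2 B}.  Implemented in the same streaming sweep as the matvec,
#' drawing each sub-edge effect when the corresponding genomic interval is
#' flushed.
#'
#' @param arg an [arg_data()] object.
#' @param tau2 variance of mutational effects per generation per bp.
#' @param seed integer seed (optional, for reproducibility).
#' @return numeric vector of genetic values, one per individual.
#' @export
simulate_genetic_values <- function(arg, tau2, seed = NULL) {
  if (tau2 < 0) stop("tau2 must be non-negative")
  g_h <- with_seed(seed, .cpp_simulate_values(
    arg$node_time, arg$edges$left, arg$edges$right,
    arg$edges$parent, arg$edges$child, arg$sequence_length,
    arg$samples, tau2))
  map <- sample_individual_map(arg)
  as.numeric(rowsum(g_h, map))
}

# Per-individual sums of mutation effects: each mutation at (position,
# node) is carried by every sample below the node in the local tree there.
mutation_genetic_values <- function(arg, effects) {
  m <- arg$mutations
  if (is.null(m)) stop("ARG carries no mutation table")
  stopifnot(length(effects) == nrow(m))
  g_h <- .cpp_mutation_values(arg$node_time, arg$edges$left, arg$edges$right,
                              arg$edges$parent, arg$edges$child,
                              arg$sequence_length, arg$samples,
                              m$position, as.integer(m$node), effects)
  map <- sample_individual_map(arg)
  as.numeric(rowsum(g_h, map))
}

#' Total root area of an ARG
#'
#' Sum over local trees of tree span times root time,
#' \eqn{\sum_T s_T t_{root,T}}, in bp-generations.  For trees with several
#' roots the root times are summed over every root that subtends at least
#' one sample; isolated sample nodes (time 0) contribute nothing.  Four
#' times this quantity bounds the generative genetic variance of a diploid
#' and is the squared phenotype scaling constant used by
#' [simulate_phenotypes()].
#'
#' @param arg an [arg_data()] object.
#' @return scalar, bp-generations.
#' @export
total_root_area <- function(arg) {
  .cpp_root_area(arg$node_time, arg$edges$left, arg$edges$right,
                 arg$edges$parent, arg$edges$child, arg$sequence_length,
                 arg$samples)$area
}

#' Number of distinct local trees
#' @param arg an [arg_data()] object.
#' @export
n_local_trees <- function(arg) {
  .cpp_root_area(arg$node_time, arg$edges$left, arg$edges$right,
                 arg$edges$parent, arg$edges$child, arg$sequence_length,
                 arg$samples)$n_trees
}
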