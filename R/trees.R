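# Oracle-scale tree iteration and sub-edge decomposition.  These routines
# materialize per-tree structure (and sub-edges) explicitly; production
# code streams edge insertions/removals instead (src/sweep.cpp).

#' Iterate over the local trees of an ARG
#'
#' Returns, for each local tree, its genomic interval and the parent array
#' of the forest on that interval.  Intended for oracles and tests; cost is
#' linear in trees times edges.
#'
#' @param arg an [arg_data()] object.
#' @return a list with one element per tree: `list(left, right, parent)`
#'   where `parent` is an integer vector indexed by `node id + 1`, with
#'   `-1` for parentless nodes, and `edge` gives the edge row (1-based)
#'   above each node or `NA`.
#' @export
local_trees <- function(arg) {
  e <- arg$edges
  n_nodes <- length(arg$node_time)
  breaks <- sort(unique(c(0, e$left, e$right, arg$sequence_length)))
  breaks <- breaks[breaks <= arg$sequence_length]
  out <- vector("list", length(breaks) - 1)
  for (t in seq_len(length(breaks) - 1)) {
    l <- breaks[t]; r <- breaks[t + 1]
    if (r <= l) next
    parent <- rep(-1L, n_nodes)
    edge_above <- rep(NA_integer_, n_nodes)
    on_tree <- which(e$left <= l & e$right >= r)
    parent[e$child[on_tree] + 1L] <- e$parent[on_tree]
    edge_above[e$child[on_tree] + 1L] <- on_tree
    out[[t]] <- list(left = l, right = r, parent = parent, edge = edge_above)
  }
  out[!vapply(out, is.null, logical(1))]
}

# Sorted sample node ids at or below each node of a tree (list per node).
samples_below <- function(parent, samples) {
  n <- length(parent)
  below <- vector("list", n)
  for (s in samples) {
    u <- s
    while (u >= 0) {
      below[[u + 1L]] <- c(below[[u + 1L]], s)
      u <- parent[u + 1L]
    }
  }
  lapply(below, sort)
}

#' Decompose ARG edges into sub-edges
#'
#' A sub-edge is a maximal fragment of an edge over which the set of sample
#' nodes descending from the edge's child is constant (no recombination in
#' the ARG below the fragment).  The union of sub-edge spans of an edge
#' recovers the edge span, and each sub-edge carries its area
#' `(right - left) * (t_parent - t_child)`.
#'
#' This explicit decomposition exists for oracles and tests; the implicit
#' matvec ([grm_matvec()]) never forms it.
#'
#' @param arg an [arg_data()] object.
#' @return a data frame with columns `parent`, `child`, `left`, `right`,
#'   `area`, `edge` (1-based row of the originating edge), plus an
#'   attribute `"samples"`: a list of the sample-node sets below each
#'   sub-edge.
#' @export
subedge_decompose <- function(arg) {
  trees <- local_trees(arg)
  e <- arg$edges
  # per tree, per present edge: descendant-set key
  recs <- list()
  for (tr in trees) {
    below <- samples_below(tr$parent, arg$samples)
    present <- which(!is.na(tr$edge))   # nodes (1-based) with a parent edge
    for (u1 in present) {
      ei <- tr$edge[u1]
      recs[[length(recs) + 1L]] <- list(
        edge = ei, left = tr$left, right = tr$right,
        key = paste(below[[u1]], collapse = ","),
        samples = below[[u1]])
    }
  }
  if (!length(recs)) {
    out <- data.frame(parent = integer(), child = integer(),
                      left = numeric(), right = numeric(),
                      area = numeric(), edge = integer())
    attr(out, "samples") <- list()
    return(out)
  }
  df <- data.frame(
    edge = vapply(recs, `[[`, 1L, "edge"),
    left = vapply(recs, `[[`, 1, "left"),
    right = vapply(recs, `[[`, 1, "right"),
    key = vapply(recs, `[[`, "", "key"),
    stringsAsFactors = FALSE)
  o <- order(df$edge, df$left)
  df <- df[o, ]
  recs <- recs[o]
  # merge consecutive tree intervals of the same edge with equal key
  grp <- integer(nrow(df))
  g <- 0L
  for (i in seq_len(nrow(df))) {
    new_grp <- i == 1 ||
      !(df$edge[i] == df$edge[i - 1] && df$key[i] == df$key[i - 1] &&
          df$left[i] == df$right[i - 1])
    if (new_grp) g <- g + 1L
    grp[i] <- g
  }
  idx <- which(!duplicated(grp))
  right <- as.numeric(tapply(df$right, grp, max))
  ei <- df$edge[idx]
  out <- data.frame(
    parent = e$parent[ei], child = e$child[ei],
    left = df$left[idx], right = right, edge = ei)
  out$area <- (out$right - out$left) *
    (arg$node_time[out$parent + 1L] - arg$node_time[out$child + 1L])
  attr(out, "samples") <- lapply(recs[idx], `[[`, "samples")
  rownames(out) <- NULL
  out
}
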