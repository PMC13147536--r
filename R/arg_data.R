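#' In-memory succinct tree sequence tables
#'
#' An `arg_data` object holds the node and edge tables that define an
#' ancestral recombination graph (ARG) and its local trees, plus the
#' grouping of sample nodes into individuals.  Conventions follow the
#' tree-sequence standard: genome positions are 0-based half-open
#' `[left, right)` in base pairs, node times are in generations increasing
#' into the past, and node ids are 0-based.
#'
#' @param node_time numeric vector of node times (one per node, node id
#'   `i` corresponds to element `i + 1`).
#' @param node_is_sample logical vector flagging sample nodes.
#' @param edges data frame with columns `left`, `right` (bp), `parent`,
#'   `child` (0-based node ids).
#' @param sequence_length genome length in bp.
#' @param individuals optional list of integer vectors grouping sample node
#'   ids into individuals (e.g. 2 per individual for diploids).  Defaults
#'   to one individual per sample node (haploid).
#' @param mutations optional data frame with columns `position` (bp) and
#'   `node` (0-based id of the node below the mutation), as produced by
#'   [simulate_arg()] with a nonzero mutation rate.
#' @return an object of class `arg_data`.
#' @seealso [load_tree_sequence()], [simulate_arg()], [grm_matvec()]
#' @export
arg_data <- function(node_time, node_is_sample, edges, sequence_length,
                     individuals = NULL, mutations = NULL) {
  stopifnot(is.numeric(node_time), is.logical(node_is_sample),
            length(node_time) == length(node_is_sample),
            is.data.frame(edges), sequence_length > 0)
  required <- c("left", "right", "parent", "child")
  if (!all(required %in% names(edges)))
    stop("edge table must have columns left, right, parent, child")
  edges <- edges[required]
  edges$parent <- as.integer(edges$parent)
  edges$child <- as.integer(edges$child)
  n_nodes <- length(node_time)

  ne <- nrow(edges)
  if (ne > 0) {
    bad <- which(edges$parent < 0 | edges$parent >= n_nodes |
                 edges$child < 0 | edges$child >= n_nodes)
    if (length(bad))
      stop("edge ", bad[1] - 1, " references a node outside the node table")
    bad <- which(node_time[edges$parent + 1L] <= node_time[edges$child + 1L])
    if (length(bad))
      stop("edge ", bad[1] - 1, " has parent time <= child time")
    bad <- which(edges$left < 0 | edges$right > sequence_length |
                 edges$left >= edges$right)
    if (length(bad))
      stop("edge ", bad[1] - 1, " has an invalid span")
    # parent-edge spans of each child must not overlap
    o <- order(edges$child, edges$left)
    same <- edges$child[o][-1] == edges$child[o][-ne]
    overlap <- same & (edges$left[o][-1] < edges$right[o][-ne])
    if (any(overlap))
      stop("edge ", o[which(overlap)[1] + 1] - 1,
           " overlaps another parent edge of the same child")
  }

  samples <- which(node_is_sample) - 1L
  if (is.null(individuals)) individuals <- as.list(samples)
  individuals <- lapply(individuals, as.integer)
  if (length(individuals)) {
    refd <- unlist(individuals)
    if (!all(refd %in% samples))
      stop("individuals reference node(s) without the sample flag: ",
           paste(setdiff(refd, samples), collapse = ", "))
  }
  if (!is.null(mutations)) {
    stopifnot(all(c("position", "node") %in% names(mutations)))
    mutations <- mutations[order(mutations$position), , drop = FALSE]
  }
  structure(list(
    node_time = as.numeric(node_time),
    node_is_sample = node_is_sample,
    edges = edges,
    sequence_length = as.numeric(sequence_length),
    individuals = individuals,
    samples = samples,
    mutations = mutations
  ), class = "arg_data")
}

#' @export
print.arg_data <- function(x, ...) {
  cat("<arg_data>", length(x$node_time), "nodes,", nrow(x$edges), "edges,",
      length(x$samples), "sample nodes,", length(x$individuals),
      "individuals,", format(x$sequence_length, big.mark = ","), "bp\n")
  invisible(x)
}

#' Number of individuals in an ARG
#' @param arg an [arg_data()] object.
#' @export
n_individuals <- function(arg) length(arg$individuals)

# individual index (1-based) of each sample node, in arg$samples order
sample_individual_map <- function(arg) {
  map <- integer(length(arg$samples))
  for (i in seq_along(arg$individuals)) {
    idx <- match(arg$individuals[[i]], arg$samples)
    map[idx] <- i
  }
  map
}

#' Read a tree sequence file into `arg_data` tables
#'
#' Uses the Python `tskit` library (found on `PATH`) to export the node,
#' edge, individual and mutation tables of a `.trees` file as delimited
#' text, then assembles them into an [arg_data()] object.
#'
#' @param path path to a `.trees` file.
#' @param python path to the Python interpreter to use.
#' @return an [arg_data()] object.
#' @export
load_tree_sequence <- function(path, python = Sys.which("python")) {
  out <- tempfile("ts_tables_")
  dir.create(out)
  on.exit(unlink(out, recursive = TRUE))
  run_python_tool("dump", c("--trees", path, "--out", out), python)
  read_arg_tables(out)
}

# Shared reader for the table directory written by inst/python/arg_tables.py
read_arg_tables <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  nodes <- read.delim(file.path(dir, "nodes.tsv"))
  edges <- read.delim(file.path(dir, "edges.tsv"))
  ind <- nodes$individual
  individuals <- NULL
  if (any(ind >= 0)) {
    smp <- nodes$id[nodes$is_sample == 1]
    grp <- ind[nodes$is_sample == 1]
    if (any(grp < 0))
      stop("sample nodes without an individual record")
    individuals <- unname(split(as.integer(smp), grp))
  }
  mut_path <- file.path(dir, "mutations.tsv")
  mutations <- if (file.exists(mut_path)) read.delim(mut_path) else NULL
  if (!is.null(mutations) && nrow(mutations) == 0) mutations <- NULL
  arg_data(node_time = nodes$time,
           node_is_sample = nodes$is_sample == 1,
           edges = edges,
           sequence_length = meta$sequence_length,
           individuals = individuals,
           mutations = mutations)
}

run_python_tool <- function(command, args, python = Sys.which("python")) {
  if (!nzchar(python))
    stop("no Python interpreter found on PATH; coalescent simulation and ",
         ".trees input require Python with msprime/tskit installed")
  script <- system.file("python", "arg_tables.py", package = "arglmm")
  res <- suppressWarnings(
    system2(python, c(shQuote(script), command, args),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("python helper failed (", command, "): ",
         paste(res, collapse = "\n"))
  invisible(res)
}
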