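#' Read a phenotype/covariate table
#'
#' Delimited text (tab or comma, autodetected) with a header.  The first
#' column is the individual id, the column named `phenotype` (or the
#' second column) holds the phenotype, and any remaining numeric columns
#' are covariates.  An intercept column is prepended when no constant
#' column is present.  Ids are matched to the ARG's individuals by
#' 0-based individual index when `arg` is given; otherwise rows are taken
#' in file order.
#'
#' @param path file path.
#' @param arg optional [arg_data()]; enables id matching and validation.
#' @return list with `y`, `X` (including intercept), `ids`.
#' @export
load_phenotypes <- function(path, arg = NULL) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, check.names = FALSE)
  if (ncol(df) < 2) stop("phenotype table needs at least id and phenotype")
  ids <- df[[1]]
  pheno_col <- if ("phenotype" %in% names(df)) "phenotype" else names(df)[2]
  y <- df[[pheno_col]]
  if (!is.numeric(y) || anyNA(y)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(y))))
    stop("missing or non-numeric phenotype in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  covars <- setdiff(names(df), c(names(df)[1], pheno_col))
  X <- if (length(covars)) as.matrix(df[covars]) else
    matrix(numeric(0), nrow(df), 0)
  if (!is.numeric(X)) stop("non-numeric covariate column(s)")
  if (anyNA(X)) stop("missing covariate values")
  if (!is.null(arg)) {
    N <- n_individuals(arg)
    idx <- match(ids, seq_len(N) - 1L)
    if (anyNA(idx))
      stop("phenotype ids not present in the tree sequence: ",
           paste(utils::head(ids[is.na(idx)], 10), collapse = ", "))
    o <- order(idx)
    ids <- ids[o]
    y <- y[o]
    X <- X[o, , drop = FALSE]
  }
  has_const <- ncol(X) > 0 &&
    any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))
  if (!has_const) X <- cbind(intercept = 1, X)
  list(y = as.numeric(y), X = X, ids = ids)
}

#' Write a fitted model as a JSON report
#'
#' @param fit a [fit_reml()] result.
#' @param path output path.
#' @export
write_fit_report <- function(fit, path) {
  report <- list(
    tau2 = fit$tau2, sigma_e2 = fit$sigma_e2,
    se = as.list(fit$se), converged = fit$converged, n_iter = fit$n_iter,
    grm_scale = fit$grm_scale,
    config = fit$config[c("cg_tol", "n_trace_vectors", "nystrom_rank",
                          "n_he_vectors", "rel_change_threshold",
                          "min_post_steps", "max_iter", "seed")],
    he_init = fit$he_init,
    history = fit$history)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a JSON fit report
#'
#' Restores the components needed for prediction (not the full fitting
#' state).
#'
#' @param path path written by [write_fit_report()].
#' @return a list of class `reml_report` usable as the `fit` argument of
#'   [predict_blup()] together with the tree sequence.
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- rep$config
  fit <- list(tau2 = rep$tau2, sigma_e2 = rep$sigma_e2,
              converged = rep$converged, grm_scale = rep$grm_scale,
              se = unlist(rep$se),
              config = reml_config(
                cg_tol = cfg$cg_tol, n_trace_vectors = cfg$n_trace_vectors,
                nystrom_rank = cfg$nystrom_rank,
                n_he_vectors = cfg$n_he_vectors,
                rel_change_threshold = cfg$rel_change_threshold,
                min_post_steps = cfg$min_post_steps,
                max_iter = cfg$max_iter,
                seed = if (is.null(cfg$seed)) NULL else cfg$seed))
  class(fit) <- c("reml_report", "reml_fit")
  fit
}

#' Write BLUP predictions as delimited text
#'
#' @param blup a [predict_blup()] result.
#' @param path output path (tab-separated).
#' @export
write_predictions <- function(blup, path) {
  df <- data.frame(individual = blup$target_index - 1L,
                   predicted = blup$predicted)
  if (!is.null(blup$conditional_variance))
    df$se <- sqrt(pmax(diag(blup$conditional_variance), 0))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
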