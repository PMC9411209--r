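#' Cost of the PCA projection of a variable subset
#'
#' Helper shared by [select_features()] and [rank_scalings()]: normalizes the
#' retained columns (centers/scales recomputed on the subset), projects onto
#' the leading `q` covariance eigenvectors, unit-box scales the scores, and
#' evaluates the aggregate manifold cost with respect to `phi`.
#'
#' @param x Raw data matrix.
#' @param cols Column names (or indices) to retain.
#' @param phi Dependent variables (fixed; never subset).
#' @param q Projection dimension.
#' @param scaling Scaling name.
#' @param options `"cost_options"`.
#' @return Aggregate cost (scalar).
#' @keywords internal
subset_projection_cost <- function(x, cols, phi, q, scaling, options) {
  xs <- normalize_data(x[, cols, drop = FALSE], scaling)
  basis <- pca_basis(xs, q = q)
  eta <- project_data(xs, basis)
  assess_manifold(eta, phi, options)$cost
}

#' Cost-guided backward feature selection
#'
#' Iteratively eliminates state variables from the data matrix so that the
#' `q`-dimensional PCA projection of the retained subset minimizes the
#' manifold cost with respect to fixed dependent variables `phi`. At each
#' iteration the removal cost is evaluated for every remaining variable
#' (scaling recomputed on each candidate subset) and the variable whose
#' removal yields the lowest cost is permanently discarded. After `Q - q`
#' iterations the subset from the iteration with the global minimum cost is
#' returned; the untouched full set is recorded as iteration 0, so the
#' algorithm can return all variables when every elimination raises the cost.
#'
#' Ties between candidate removals are broken toward the lower column index
#' (and noted in the trace); a candidate whose subset yields a degenerate
#' scaling is skipped with a warning.
#'
#' @param x Raw data matrix, N x Q.
#' @param phi Dependent variables, fixed throughout (targets are not removed
#'   from `phi` even if their source column leaves `x`).
#' @param q Target manifold dimension, `q <= Q` (with `q = Q` no variable can
#'   be eliminated and the full set is returned from iteration 0).
#' @param scaling Scaling name applied (recomputed) to every candidate subset.
#' @param options A `"cost_options"` object.
#' @param verbose Print per-iteration progress.
#' @return Object of class `"feature_selection"`: list with `iterations`
#'   (data frame: iteration, removed, cost, n_retained), `remaining` (list of
#'   retained-name vectors per iteration), `best_iteration`, `optimal_subset`,
#'   `optimal_cost`.
#' @export
select_features <- function(x, phi, q, scaling = "Auto",
                            options = cost_options(), verbose = FALSE) {
  x <- as_data_matrix(x)
  phi <- .as_phi_matrix(phi)
  Q <- ncol(x)
  if (q > Q) stop("q cannot exceed the number of variables Q = ", Q,
                  call. = FALSE)

  retained <- colnames(x)
  it_removed <- NA_character_
  it_cost <- subset_projection_cost(x, retained, phi, q, scaling, options)
  remaining <- list(retained)
  if (verbose) message("iteration 0 (full set): cost = ", signif(it_cost, 4))

  for (it in seq_len(Q - q)) {
    cand_cost <- rep(NA_real_, length(retained))
    for (ci in seq_along(retained)) {
      sub <- retained[-ci]
      cand_cost[ci] <- tryCatch(
        subset_projection_cost(x, sub, phi, q, scaling, options),
        error = function(e) {
          warning("skipping removal of '", retained[ci], "': ",
                  conditionMessage(e), call. = FALSE)
          NA_real_
        })
    }
    if (all(is.na(cand_cost))) {
      warning("no feasible removal at iteration ", it, "; stopping early",
              call. = FALSE)
      break
    }
    best <- which(cand_cost == min(cand_cost, na.rm = TRUE))
    if (length(best) > 1L) {
      message("tie between removals {",
              paste(retained[best], collapse = ", "),
              "}; removing the lowest-index column")
    }
    best <- best[1L]
    if (verbose) message("iteration ", it, ": removing '", retained[best],
                         "', cost = ", signif(cand_cost[best], 4))
    it_removed <- c(it_removed, retained[best])
    it_cost <- c(it_cost, cand_cost[best])
    retained <- retained[-best]
    remaining <- c(remaining, list(retained))
  }

  iterations <- data.frame(iteration = seq_along(it_cost) - 1L,
                           removed = it_removed,
                           cost = it_cost,
                           n_retained = lengths(remaining),
                           stringsAsFactors = FALSE)
  best_it <- which.min(it_cost)
  structure(list(iterations = iterations,
                 remaining = remaining,
                 best_iteration = best_it - 1L,
                 optimal_subset = remaining[[best_it]],
                 optimal_cost = it_cost[best_it]),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("Cost-guided backward feature selection\n")
  df <- x$iterations
  df$cost <- signif(df$cost, 4)
  print(df, row.names = FALSE)
  cat("Optimal subset (iteration ", x$best_iteration, ", cost ",
      signif(x$optimal_cost, 4), "): ",
      paste(x$optimal_subset, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a feature-selection trace
#'
#' The per-iteration table goes to `<prefix>.tsv` and a JSON summary naming
#' the optimal subset to `<prefix>.json`.
#'
#' @param trace A `"feature_selection"` object.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_feature_selection <- function(trace, prefix) {
  stopifnot(inherits(trace, "feature_selection"))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(trace$iterations, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(best_iteration = trace$best_iteration,
                            optimal_cost = trace$optimal_cost,
                            optimal_subset = trace$optimal_subset),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, json))
}

#' Rank scaling methods by projection cost
#'
#' Evaluates, for each requested scaling, the manifold cost of the
#' `q`-dimensional PCA projection of the scaled data with respect to `phi`,
#' and returns the methods ordered from best (lowest cost) to worst. Scalings
#' that are degenerate for the data (e.g. Poisson on negative columns) are
#' dropped with a warning.
#'
#' @param x Raw data matrix.
#' @param phi Dependent variables.
#' @param q Projection dimension.
#' @param methods Scaling names to try (default all thirteen).
#' @param options A `"cost_options"` object.
#' @return Data frame with columns `scaling` and `cost`, sorted ascending.
#' @export
rank_scalings <- function(x, phi, q, methods = scaling_methods(),
                          options = cost_options()) {
  x <- as_data_matrix(x)
  phi <- .as_phi_matrix(phi)
  costs <- vapply(methods, function(m) {
    tryCatch(subset_projection_cost(x, colnames(x), phi, q, m, options),
             error = function(e) {
               warning("scaling '", m, "' skipped: ", conditionMessage(e),
                       call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  out <- data.frame(scaling = methods, cost = costs, stringsAsFactors = FALSE)
  out <- out[!is.na(out$cost), , drop = FALSE]
  out[order(out$cost), , drop = FALSE]
}
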