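#' Cost function options
#'
#' @param r Penalty power >= 0 on the log-distance from the rightmost peak
#'   (default 1). Larger `r` amplifies variance at scales far below the main
#'   feature, the signature of non-uniqueness.
#' @param b Vertical-shift weight >= 0 (default 1). Larger `b` penalizes a
#'   small largest-feature size more.
#' @param norm Aggregation norm over per-variable costs: `"L1"` (sum of
#'   absolute values, default), `"L2"`, or `"max"`.
#' @param peak_shift Fraction p in \[0, 1) shifting the effective peak toward
#'   the top of the sigma grid in log space (default 0).
#' @param grid A `"sigma_grid"` (default [sigma_grid()]).
#' @return Object of class `"cost_options"`.
#' @export
cost_options <- function(r = 1, b = 1, norm = c("L1", "L2", "max"),
                         peak_shift = 0, grid = sigma_grid()) {
  stopifnot(r >= 0, b >= 0, peak_shift >= 0, peak_shift < 1)
  norm <- match.arg(norm)
  structure(list(r = r, b = b, norm = norm, peak_shift = peak_shift,
                 grid = .as_sigma_grid(grid)),
            class = "cost_options")
}

#' Penalty function over the sigma grid
#'
#' \deqn{P(\sigma) = |\tilde{\sigma} - \tilde{\sigma}_{peak}|^r +
#'       b \frac{\tilde{\sigma}_{max} - \tilde{\sigma}_{min}}
#'              {\tilde{\sigma}_{peak} - \tilde{\sigma}_{min}},}
#' where tildes denote log10 quantities. The first term grows with log
#' distance from the rightmost peak, amplifying variance at scales far below
#' the largest feature; the second is a constant shift that rewards a large
#' \eqn{\sigma_{peak}}.
#'
#' @param grid A `"sigma_grid"`.
#' @param log_sigma_peak Peak location in log10 space (possibly shifted),
#'   strictly above the grid's log minimum.
#' @param r,b Hyper-parameters, see [cost_options()].
#' @return Numeric vector of penalty values per grid point.
#' @export
penalty_curve <- function(grid, log_sigma_peak, r = 1, b = 1) {
  grid <- .as_sigma_grid(grid)
  lg <- grid$log_values
  lg_min <- lg[1L]
  lg_max <- lg[length(lg)]
  if (log_sigma_peak <= lg_min) {
    stop("degenerate peak at the bottom of the sigma grid (log10 sigma_peak = ",
         signif(log_sigma_peak, 4), "); vertical-shift term undefined",
         call. = FALSE)
  }
  abs(lg - log_sigma_peak)^r + b * (lg_max - lg_min) / (log_sigma_peak - lg_min)
}

#' Area under a curve in log10 sigma space
#'
#' Composite trapezoid integral of curve values over log10(sigma), so scales
#' of variation with different orders of magnitude contribute equally.
#'
#' @param values Numeric curve values on the grid.
#' @param grid A `"sigma_grid"`.
#' @return The area (scalar).
#' @export
curve_area <- function(values, grid) {
  grid <- .as_sigma_grid(grid)
  stopifnot(length(values) == length(grid$values))
  pracma::trapz(grid$log_values, values)
}

#' Per-variable cost
#'
#' Trapezoid integral of the penalized derivative curve,
#' \eqn{L_i = \int P(\sigma, \sigma_{peak,i}) \hat{D}_i(\sigma)
#' \, d\tilde{\sigma}}.
#'
#' @param dhat Max-normalized derivative curve values on the grid.
#' @param grid A `"sigma_grid"`.
#' @param log_sigma_peak Peak location in log10 space.
#' @param options A `"cost_options"` object.
#' @return The cost (scalar).
#' @export
cost_variable <- function(dhat, grid, log_sigma_peak, options = cost_options()) {
  grid <- .as_sigma_grid(grid)
  p <- penalty_curve(grid, log_sigma_peak, r = options$r, b = options$b)
  pracma::trapz(grid$log_values, p * dhat)
}

#' Aggregate per-variable costs
#'
#' @param costs Numeric vector of per-variable costs (length >= 1).
#' @param norm `"L1"` (sum of absolute values), `"L2"`, or `"max"`.
#' @return The aggregate cost (scalar).
#' @export
aggregate_cost <- function(costs, norm = "L1") {
  if (length(costs) == 0L) stop("no per-variable costs to aggregate", call. = FALSE)
  switch(match.arg(norm, c("L1", "L2", "max")),
         L1 = sum(abs(costs)),
         L2 = sqrt(sum(costs^2)),
         max = max(abs(costs)))
}

#' Assess a manifold parameterization
#'
#' Runs the full pipeline for a set of manifold parameters and dependent
#' variables: unit-box scaling of the coordinates, normalized variance over
#' the sigma grid, scale-space derivative, rightmost-peak detection, penalized
#' integration into per-variable costs \eqn{L_i}, and aggregation into a
#' single manifold cost \eqn{L}. Lower cost indicates a better-behaved
#' parameterization; costs are comparable between manifolds assessed with the
#' same options, not in absolute terms.
#'
#' @param params `"manifold_params"` or coordinate matrix (any embedding:
#'   PCA scores, t-SNE, UMAP, ad hoc coordinates). Unit-box scaling is applied
#'   automatically.
#' @param phi Dependent variables (vector or N x m matrix). Class labels may
#'   be passed as numeric values; note that the numeric spacing between labels
#'   then affects the cost.
#' @param options A `"cost_options"` object.
#' @return Object of class `"cost_report"`: list with `variables` (data frame
#'   with columns name, cost, sigma_peak, area), `cost` (aggregate),
#'   `options`, and `curves` (the `"variance_curves"` object).
#' @examples
#' toy <- toy_overlap(d = 0)
#' rep0 <- assess_manifold(toy$eta, toy$phi,
#'                         cost_options(grid = sigma_grid(n = 50)))
#' rep0$cost
#' @export
assess_manifold <- function(params, phi, options = cost_options()) {
  stopifnot(inherits(options, "cost_options"))
  curves <- normalized_variance(params, phi, options$grid)
  curves <- variance_derivative(curves)
  m <- length(curves$phi_names)
  costs <- numeric(m)
  peaks <- numeric(m)
  areas <- numeric(m)
  for (i in seq_len(m)) {
    pk <- find_sigma_peak(curves$Dhat[, i], options$grid, options$peak_shift)
    peaks[i] <- pk$sigma_peak
    areas[i] <- curve_area(curves$Dhat[, i], options$grid)
    costs[i] <- cost_variable(curves$Dhat[, i], options$grid,
                              pk$log_sigma_peak, options)
  }
  structure(list(variables = data.frame(name = curves$phi_names,
                                        cost = costs,
                                        sigma_peak = peaks,
                                        area = areas,
                                        stringsAsFactors = FALSE),
                 cost = aggregate_cost(costs, options$norm),
                 options = options,
                 curves = curves),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Manifold topology cost (r = ", x$options$r, ", b = ", x$options$b,
      ", norm = ", x$options$norm, ")\n", sep = "")
  df <- x$variables
  df$cost <- signif(df$cost, 2)
  df$sigma_peak <- signif(df$sigma_peak, 2)
  df$area <- signif(df$area, 2)
  print(df, row.names = FALSE)
  cat("Aggregate cost L =", signif(x$cost, 2), "\n")
  invisible(x)
}

#' Serialize a cost report to JSON
#'
#' @param report A `"cost_report"`.
#' @param path Output file path.
#' @param provenance Optional named list recorded verbatim (input files, seed,
#'   scaling, dimension, subsampling).
#' @return `path`, invisibly.
#' @export
write_cost_report <- function(report, path, provenance = NULL) {
  stopifnot(inherits(report, "cost_report"))
  obj <- list(
    options = list(r = report$options$r, b = report$options$b,
                   norm = report$options$norm,
                   peak_shift = report$options$peak_shift,
                   sigma_min = min(report$options$grid$values),
                   sigma_max = max(report$options$grid$values),
                   sigma_num = length(report$options$grid$values)),
    per_variable = report$variables,
    aggregate_cost = report$cost,
    provenance = provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
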