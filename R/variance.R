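#' Logarithmic bandwidth grid
#'
#' The sweep of manifold length scales sigma at which the normalized variance
#' is evaluated. The default grid, 200 points logarithmically spaced over
#' \eqn{[10^{-7}, 10^{3}]}, comfortably brackets the feature sizes of
#' unit-box-scaled manifolds.
#'
#' @param sigma_min,sigma_max Positive endpoints, `sigma_min < sigma_max`.
#' @param n Number of grid points (>= 3).
#' @return Object of class `"sigma_grid"`: list with `values` (increasing) and
#'   `log_values` (log10).
#' @export
sigma_grid <- function(sigma_min = 1e-7, sigma_max = 1e3, n = 200) {
  stopifnot(sigma_min > 0, sigma_max > sigma_min, n >= 3)
  lg <- seq(log10(sigma_min), log10(sigma_max), length.out = n)
  structure(list(values = 10^lg, log_values = lg), class = "sigma_grid")
}

.as_sigma_grid <- function(grid) {
  if (inherits(grid, "sigma_grid")) return(grid)
  stopifnot(is.numeric(grid), all(grid > 0), !is.unsorted(grid, strictly = TRUE))
  structure(list(values = as.numeric(grid), log_values = log10(grid)),
            class = "sigma_grid")
}

.as_phi_matrix <- function(phi) {
  if (is.list(phi) && !is.null(phi$values) && !is.data.frame(phi)) phi <- phi$values
  phi <- as.matrix(phi)
  if (!is.numeric(phi) || !all(is.finite(phi))) {
    stop("dependent variables must be finite numerics", call. = FALSE)
  }
  if (is.null(colnames(phi))) colnames(phi) <- paste0("phi", seq_len(ncol(phi)))
  phi
}

#' Gaussian-kernel weighted average on a manifold
#'
#' Evaluates \eqn{K(\eta, \sigma) = \sum_j w_j \phi_j / \sum_j w_j} with
#' weights \eqn{w_j = \exp(-\|\eta_j - \eta\|_2^2 / \sigma^2)} at arbitrary
#' query locations. If every weight underflows to zero at a query (possible
#' for tiny sigma and a query far from all observations), the value of the
#' nearest observation is returned instead — the mathematical sigma-to-zero
#' limit — with a warning.
#'
#' @param query Numeric matrix (or vector) of query locations in manifold
#'   coordinates.
#' @param sigma Positive bandwidth.
#' @param params `"manifold_params"` (unit-box scaled recommended) or matrix.
#' @param phi Numeric vector/matrix of dependent-variable observations.
#' @return Matrix of estimates, one row per query, one column per variable.
#' @export
kernel_estimate <- function(query, sigma, params, phi) {
  stopifnot(sigma > 0)
  eta <- if (inherits(params, "manifold_params")) params$values else as.matrix(params)
  if (is.null(dim(query))) query <- matrix(query, ncol = ncol(eta))
  query <- as.matrix(query)
  phi <- .as_phi_matrix(phi)
  stopifnot(nrow(phi) == nrow(eta), ncol(query) == ncol(eta))
  out <- cpp_kernel_estimate(query, eta, phi, sigma)
  bad <- which(!is.finite(out[, 1L]))
  if (length(bad)) {
    warning("all kernel weights underflowed for ", length(bad),
            " query point(s); using the nearest observation", call. = FALSE)
    for (a in bad) {
      d2 <- rowSums(sweep(eta, 2L, query[a, ], "-")^2)
      out[a, ] <- phi[which.min(d2), ]
    }
  }
  colnames(out) <- colnames(phi)
  out
}

#' Normalized variance of dependent variables across length scales
#'
#' For every bandwidth sigma on the grid and every dependent variable
#' \eqn{\phi_i}, computes
#' \deqn{N_i(\sigma) = \frac{\sum_k (\phi_{k,i} - K_i(\eta_k, \sigma))^2}
#'                          {\sum_k (\phi_{k,i} - \bar{\phi}_i)^2},}
#' the kernel-smoothed residual variance relative to the total variance.
#' \eqn{N_i} tends to 0 as sigma shrinks below the data spacing (each point
#' predicts itself) and to 1 as sigma exceeds the manifold diameter (the
#' kernel average becomes the global mean). Structure that cannot be resolved
#' at any bandwidth — overlapping manifold states carrying different
#' \eqn{\phi} values — keeps \eqn{N_i} away from 0 at small sigma.
#'
#' @param params `"manifold_params"`; unit-box scaled automatically when not
#'   already flagged as such.
#' @param phi Dependent variables, N x m matrix or vector; each column must be
#'   non-constant.
#' @param grid A `"sigma_grid"` (default [sigma_grid()]).
#' @return Object of class `"variance_curves"`: list with `sigma` (the grid),
#'   `N` (S x m matrix), `phi_names`.
#' @export
normalized_variance <- function(params, phi, grid = sigma_grid()) {
  if (!inherits(params, "manifold_params")) params <- manifold_params(params)
  if (!params$unit_box_scaled) params <- unit_box_scale(params)
  phi <- .as_phi_matrix(phi)
  grid <- .as_sigma_grid(grid)
  if (nrow(phi) != nrow(params$values)) {
    stop("eta and phi row counts differ", call. = FALSE)
  }
  spread <- apply(phi, 2L, function(v) max(v) - min(v))
  if (any(spread == 0)) {
    stop("dependent variable(s) constant (zero total variance): ",
         paste(colnames(phi)[spread == 0], collapse = ", "), call. = FALSE)
  }
  N <- cpp_normalized_variance(params$values, phi, grid$values)
  colnames(N) <- colnames(phi)
  structure(list(sigma = grid, N = N, phi_names = colnames(phi)),
            class = "variance_curves")
}

#' Scale-space derivative of the normalized variance
#'
#' Adds to a `"variance_curves"` object the derivative
#' \eqn{D_i(\sigma) = dN_i/d\log_{10}\sigma + \lim_{\sigma \to 0} N_i(\sigma)}
#' and its max-normalized form \eqn{\hat{D}_i = D_i / \max D_i}. The zero
#' limit is approximated by the value at the smallest grid sigma, which for
#' the default grid sits far below any unit-box data spacing; a nonzero limit
#' is the signature of non-uniqueness. Derivatives use central differences on
#' the uniform log10 grid, one-sided at the endpoints.
#'
#' @param curves A `"variance_curves"` object from [normalized_variance()].
#' @return The same object with components `D`, `Dhat`, `limit_at_zero` added.
#' @export
variance_derivative <- function(curves) {
  stopifnot(inherits(curves, "variance_curves"))
  lg <- curves$sigma$log_values
  N <- curves$N
  if (nrow(N) < 3L) stop("need at least 3 grid points", call. = FALSE)
  dN <- apply(N, 2L, .grad_uniform, h = lg[2L] - lg[1L])
  lim0 <- N[1L, ]
  D <- sweep(dN, 2L, lim0, "+")
  dmax <- apply(D, 2L, max)
  if (any(dmax <= 0)) {
    stop("flat variance curve with non-positive derivative maximum for: ",
         paste(curves$phi_names[dmax <= 0], collapse = ", "), call. = FALSE)
  }
  curves$D <- D
  curves$Dhat <- sweep(D, 2L, dmax, "/")
  curves$limit_at_zero <- lim0
  curves
}

# central differences on a uniform grid with one-sided endpoints
.grad_uniform <- function(y, h) {
  n <- length(y)
  g <- numeric(n)
  g[1L] <- (y[2L] - y[1L]) / h
  g[n] <- (y[n] - y[n - 1L]) / h
  if (n > 2L) g[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (2 * h)
  g
}

#' Rightmost peak of a derivative curve
#'
#' Finds all local maxima of the discrete curve by neighbour comparison (on a
#' plateau, the rightmost plateau index counts) and returns the rightmost
#' one, which marks the largest feature size on the manifold. Local maxima
#' whose height falls below `noise_floor` times the curve maximum are
#' ignored: in the flat regions where the variance curve has saturated, the
#' finite-difference derivative is pure round-off (~1e-10 relative), and the
#' floor of 1e-4 sits far above that while remaining far below any genuine
#' rise. If no qualifying interior local maximum exists the rightmost grid
#' argmax is used. With `peak_shift` p > 0 the reported location moves toward
#' the top of the grid in log space:
#' \eqn{\tilde{\sigma}_{eff} = \tilde{\sigma}_{peak} +
#' p(\tilde{\sigma}_{max} - \tilde{\sigma}_{peak})}.
#'
#' @param dhat Numeric vector of curve values on the grid (typically a
#'   `Dhat` column).
#' @param grid A `"sigma_grid"`.
#' @param peak_shift Fraction p in \[0, 1).
#' @param noise_floor Minimum peak height as a fraction of the curve maximum
#'   (default 1e-4).
#' @return List with `sigma_peak` (grid value of the rightmost peak),
#'   `log_sigma_peak` (after the shift), `peak_index`, `peak_indices` (all
#'   qualifying local maxima).
#' @export
find_sigma_peak <- function(dhat, grid, peak_shift = 0, noise_floor = 1e-4) {
  grid <- .as_sigma_grid(grid)
  stopifnot(length(dhat) == length(grid$values),
            peak_shift >= 0, peak_shift < 1)
  peaks <- .local_maxima(dhat)
  peaks <- peaks[dhat[peaks] >= noise_floor * max(dhat)]
  idx <- if (length(peaks)) max(peaks) else max(which(dhat == max(dhat)))
  lg_peak <- grid$log_values[idx]
  lg_eff <- lg_peak + peak_shift * (grid$log_values[length(dhat)] - lg_peak)
  list(sigma_peak = grid$values[idx],
       log_sigma_peak = lg_eff,
       peak_index = idx,
       peak_indices = peaks)
}

# interior local maxima by neighbour comparison; plateaus count once, at
# their rightmost index
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  out <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L  # walk the plateau
      if (j < n && y[j + 1L] < y[j]) out <- c(out, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' @export
print.variance_curves <- function(x, ...) {
  cat("Normalized variance curves: ", length(x$phi_names), " variable(s), ",
      length(x$sigma$values), " sigma values in [",
      format(min(x$sigma$values)), ", ", format(max(x$sigma$values)), "]\n",
      sep = "")
  if (!is.null(x$Dhat)) cat("  derivative curves computed\n")
  invisible(x)
}

#' Export variance curves as a table
#'
#' One row per grid point; columns `sigma`, then `N_<name>` and (when
#' computed) `Dhat_<name>` per dependent variable.
#'
#' @param curves A `"variance_curves"` object.
#' @param path Optional file path; when given the table is written as TSV.
#' @return The data frame, invisibly when written.
#' @export
curves_table <- function(curves, path = NULL) {
  stopifnot(inherits(curves, "variance_curves"))
  df <- data.frame(sigma = curves$sigma$values)
  for (nm in curves$phi_names) df[[paste0("N_", nm)]] <- curves$N[, nm]
  if (!is.null(curves$Dhat)) {
    for (nm in curves$phi_names) df[[paste0("Dhat_", nm)]] <- curves$Dhat[, nm]
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
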