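#' Principal-component outlier classifier
#'
#' Flags observations with anomalous scores on the leading (major) or trailing
#' (minor) principal components of the Auto-scaled data. Two statistics are
#' computed per observation i: the sum of squared PC scores over the major PCs,
#' each divided by its eigenvalue, and the analogous sum over the minor PCs.
#' An observation is an outlier if either statistic exceeds the empirical
#' `quantile` of that statistic's distribution.
#'
#' Major PCs are the smallest leading set whose cumulative variance explained
#' reaches `major_variance_fraction`; minor PCs are the smallest trailing set
#' whose variance explained reaches `minor_variance_fraction` (counted from the
#' last PC backwards).
#'
#' @param x Numeric data matrix (N x Q), raw units; Auto scaling is applied
#'   internally before PCA.
#' @param major_variance_fraction Cumulative variance target for the major PC
#'   set (default 0.5).
#' @param minor_variance_fraction Tail variance target for the minor PC set
#'   (default 0.2).
#' @param quantile Probability in (0,1\] for the empirical thresholds
#'   (default 0.98); at 1 the thresholds equal the statistic maxima and no
#'   observation is flagged.
#' @return An object of class `"outlier_result"`: list with `outlier_indices`,
#'   `major_statistic`, `minor_statistic`, `thresholds` (c1, c2),
#'   `n_major_pcs`, `minor_start_index`.
#' @export
detect_outliers <- function(x, major_variance_fraction = 0.5,
                            minor_variance_fraction = 0.2, quantile = 0.98) {
  x <- as_data_matrix(x)
  if (!(quantile > 0 && quantile <= 1)) {
    stop("quantile must lie in (0, 1]", call. = FALSE)
  }
  xs <- normalize_data(x, "Auto")
  q_tot <- ncol(xs)
  basis <- pca_basis(xs, q = q_tot)
  z <- project_data(xs, basis)$values
  ev <- basis$eigenvalues
  frac <- ev / sum(ev)

  q_major <- which(cumsum(frac) >= major_variance_fraction)[1L]
  # trailing PCs explaining >= minor_variance_fraction, counted from the tail
  tail_cum <- rev(cumsum(rev(frac)))
  k_minor <- max(which(tail_cum >= minor_variance_fraction))

  major_set <- seq_len(q_major)
  minor_set <- seq(k_minor, q_tot)
  if (any(ev[major_set] <= 0) || any(ev[minor_set] <= 0)) {
    stop("non-positive PCA eigenvalue in a classifier divisor; ",
         "data may be rank-deficient", call. = FALSE)
  }

  major_stat <- rowSums(sweep(z[, major_set, drop = FALSE]^2, 2L,
                              ev[major_set], "/"))
  minor_stat <- rowSums(sweep(z[, minor_set, drop = FALSE]^2, 2L,
                              ev[minor_set], "/"))
  c1 <- stats::quantile(major_stat, probs = quantile, names = FALSE, type = 7)
  c2 <- stats::quantile(minor_stat, probs = quantile, names = FALSE, type = 7)
  flagged <- which(major_stat > c1 | minor_stat > c2)

  structure(list(outlier_indices = flagged,
                 major_statistic = major_stat,
                 minor_statistic = minor_stat,
                 thresholds = c(c1 = c1, c2 = c2),
                 n_major_pcs = q_major,
                 minor_start_index = k_minor),
            class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat("PC outlier classifier: ", length(x$outlier_indices), " of ",
      length(x$major_statistic), " observations flagged\n", sep = "")
  cat("  major PCs: 1..", x$n_major_pcs, "  minor PCs: ",
      x$minor_start_index, "..end\n", sep = "")
  cat("  thresholds: c1 = ", signif(x$thresholds[["c1"]], 4),
      ", c2 = ", signif(x$thresholds[["c2"]], 4), "\n", sep = "")
  invisible(x)
}

#' Uniform subsample of observations
#'
#' Draws `n` rows uniformly without replacement, reproducibly for a fixed
#' seed. Intended to ease the O(N^2) cost of the variance sweep on large
#' datasets.
#'
#' @param x Numeric data matrix.
#' @param n Number of rows to keep, `2 <= n <= nrow(x)`.
#' @param seed Integer seed (default 100).
#' @return The sampled matrix; attribute `"subsampled"` is `TRUE` when
#'   `n < nrow(x)` and the attribute `"rows"` holds the selected indices.
#' @export
subsample <- function(x, n, seed = 100) {
  x <- as_data_matrix(x)
  if (n < 2 || n > nrow(x)) {
    stop("n must satisfy 2 <= n <= N = ", nrow(x), call. = FALSE)
  }
  rows <- withr_seed(seed, sample.int(nrow(x), size = n, replace = FALSE))
  out <- x[rows, , drop = FALSE]
  attr(out, "rows") <- rows
  attr(out, "subsampled") <- n < nrow(x)
  out
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
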