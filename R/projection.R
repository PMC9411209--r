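#' PCA basis of a (pre-normalized) data matrix
#'
#' Computes the leading `q` eigenvectors of the data covariance matrix. The
#' data is expected to be normalized already (see [normalize_data()]); no
#' centering or scaling is applied here beyond the covariance definition.
#' Eigenvector signs are fixed by forcing the largest-magnitude component of
#' each column to be positive, so the basis is reproducible across
#' eigensolvers.
#'
#' @param x Numeric matrix, N x Q.
#' @param q Target dimension, `1 <= q <= Q`.
#' @return An object of class `"linear_basis"`: list with `vectors` (Q x q,
#'   orthonormal columns), `eigenvalues` (length q, non-increasing),
#'   `dimension_names`.
#' @export
pca_basis <- function(x, q) {
  x <- as_data_matrix(x)
  Q <- ncol(x)
  if (!(q >= 1 && q <= Q)) stop("q must satisfy 1 <= q <= Q = ", Q, call. = FALSE)
  eig <- eigen(stats::cov(x), symmetric = TRUE)
  vectors <- eig$vectors[, seq_len(q), drop = FALSE]
  # sign convention: largest-magnitude component positive
  for (j in seq_len(q)) {
    i_max <- which.max(abs(vectors[, j]))
    if (vectors[i_max, j] < 0) vectors[, j] <- -vectors[, j]
  }
  rownames(vectors) <- colnames(x)
  colnames(vectors) <- paste0("eta", seq_len(q))
  structure(list(vectors = vectors,
                 eigenvalues = pmax(eig$values[seq_len(q)], 0),
                 dimension_names = colnames(vectors)),
            class = "linear_basis")
}

#' Project data onto a linear basis
#'
#' Computes the manifold parameters `eta = X A`. Normalization is upstream;
#' no centering is applied here.
#'
#' @param x Numeric matrix whose columns match the basis rows.
#' @param basis A `"linear_basis"` (or any Q x q matrix).
#' @return A `"manifold_params"` object: list with `values` (N x q),
#'   `dimension_names`, `unit_box_scaled = FALSE`.
#' @export
project_data <- function(x, basis) {
  x <- as_data_matrix(x)
  A <- if (inherits(basis, "linear_basis")) basis$vectors else as.matrix(basis)
  if (ncol(x) != nrow(A)) {
    stop("data has ", ncol(x), " columns but basis has ", nrow(A), " rows",
         call. = FALSE)
  }
  eta <- x %*% A
  if (is.null(colnames(eta))) colnames(eta) <- paste0("eta", seq_len(ncol(eta)))
  manifold_params(eta, unit_box_scaled = FALSE)
}

#' Construct manifold parameters from a coordinate matrix
#'
#' Wraps an N x q matrix of embedding coordinates (from PCA, t-SNE, UMAP or
#' any other source) into the container consumed by the variance and cost
#' functions.
#'
#' @param values Numeric matrix of coordinates, one observation per row.
#' @param unit_box_scaled Logical; set `TRUE` only if every column already
#'   spans exactly \[0, 1\].
#' @return Object of class `"manifold_params"`.
#' @export
manifold_params <- function(values, unit_box_scaled = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("manifold parameters must be finite numerics", call. = FALSE)
  }
  if (is.null(colnames(values))) colnames(values) <- paste0("eta", seq_len(ncol(values)))
  structure(list(values = values,
                 dimension_names = colnames(values),
                 unit_box_scaled = isTRUE(unit_box_scaled)),
            class = "manifold_params")
}

#' Min-max scale manifold parameters to the unit box
#'
#' Scales every coordinate to \[0, 1\] so the kernel bandwidth sigma has the
#' same meaning in each manifold dimension. Idempotent. A degenerate
#' (constant) column is mapped to 0.5 with a warning, so it contributes zero
#' to all pairwise distances.
#'
#' @param params A `"manifold_params"` object or coordinate matrix.
#' @return Unit-box scaled `"manifold_params"`.
#' @export
unit_box_scale <- function(params) {
  if (!inherits(params, "manifold_params")) params <- manifold_params(params)
  if (params$unit_box_scaled) return(params)
  v <- params$values
  for (j in seq_len(ncol(v))) {
    rng <- range(v[, j])
    if (rng[1] == rng[2]) {
      warning("manifold dimension '", colnames(v)[j],
              "' is constant; mapped to 0.5", call. = FALSE)
      v[, j] <- 0.5
    } else {
      v[, j] <- (v[, j] - rng[1]) / (rng[2] - rng[1])
    }
  }
  manifold_params(v, unit_box_scaled = TRUE)
}

#' @export
print.manifold_params <- function(x, ...) {
  cat("Manifold parameters: ", nrow(x$values), " observations x ",
      ncol(x$values), " dimensions (",
      if (x$unit_box_scaled) "unit-box scaled" else "raw", ")\n", sep = "")
  invisible(x)
}
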