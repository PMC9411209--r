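#' Supported scaling method names
#'
#' The thirteen per-column centering/scaling schemes understood by
#' [scaling_spec()]. Names are matched case-insensitively; `"0-1"` and
#' `"-1-1"` are accepted aliases for `"ZeroToOne"` and `"MinusOneToOne"`.
#'
#' @return Character vector of canonical method names.
#' @export
scaling_methods <- function() {
  c("None", "Auto", "Pareto", "VAST", "Range", "ZeroToOne", "MinusOneToOne",
    "Level", "Max", "Poisson", "S1", "S2", "S3")
}

# population (ddof = 0) standard deviation, per column
.pop_sd <- function(x) {
  n <- nrow(x)
  apply(x, 2L, function(v) sqrt(sum((v - mean(v))^2) / n))
}

# raw (non-excess, Pearson) kurtosis m4 / m2^2; equals 3 for a Gaussian
.raw_kurtosis <- function(x) {
  apply(x, 2L, function(v) {
    m <- mean(v)
    m2 <- mean((v - m)^2)
    mean((v - m)^4) / m2^2
  })
}

.match_scaling <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  aliases <- c("0-1" = "ZeroToOne", "0,1" = "ZeroToOne",
               "-1-1" = "MinusOneToOne", "-1,1" = "MinusOneToOne",
               "zero_to_one" = "ZeroToOne", "minus_one_to_one" = "MinusOneToOne")
  key <- tolower(trimws(name))
  canon <- scaling_methods()
  hit <- match(key, tolower(canon))
  if (is.na(hit)) {
    ali <- match(key, tolower(names(aliases)))
    if (is.na(ali)) {
      stop("unknown scaling method '", name, "'; supported: ",
           paste(canon, collapse = ", "), call. = FALSE)
    }
    return(unname(aliases[[ali]]))
  }
  canon[hit]
}

#' Compute centers and scales for a data matrix
#'
#' Evaluates one of the thirteen supported per-column scaling schemes on a
#' numeric matrix: the classical chemometrics scalings (Auto, Pareto, VAST,
#' Range, Level, Max, Poisson, interval scalings to \[0,1\] and \[-1,1\]) and
#' the kurtosis-augmented VAST variants S1--S3, in which the VAST scale
#' \eqn{s_j^2/\bar{X}_j} is multiplied by the squared raw kurtosis and the
#' denominator mean is replaced by the column maximum (S2) or range (S3).
#'
#' Standard deviations use the population convention (divisor `N`); kurtosis
#' is the raw fourth standardized moment (3 for a Gaussian column), so
#' Gaussian data does not produce zero S1--S3 scales.
#'
#' @param x Numeric matrix (observations in rows) or data frame of numerics.
#' @param method Scaling name, case-insensitive; see [scaling_methods()].
#' @return An object of class `"scaling_spec"`: list with `method`, `centers`,
#'   `scales` (named per column).
#' @examples
#' x <- cbind(a = c(1, 2, 3), b = c(10, 20, 40))
#' scaling_spec(x, "auto")
#' @export
scaling_spec <- function(x, method = "Auto") {
  x <- as_data_matrix(x)
  method <- .match_scaling(method)
  q <- ncol(x)
  mu <- colMeans(x)
  if (method == "None") {
    centers <- rep(0, q)
    scales <- rep(1, q)
  } else {
    s <- .pop_sd(x)
    mx <- apply(x, 2L, max)
    mn <- apply(x, 2L, min)
    rng <- mx - mn
    centers <- switch(method,
      ZeroToOne = mn,
      MinusOneToOne = (mx + mn) / 2,
      mu)
    scales <- switch(method,
      Auto = s,
      Pareto = sqrt(s),
      VAST = s^2 / mu,
      Range = rng,
      ZeroToOne = rng,
      MinusOneToOne = rng / 2,
      Level = mu,
      Max = mx,
      Poisson = sqrt(mu),
      S1 = s^2 * .raw_kurtosis(x)^2 / mu,
      S2 = s^2 * .raw_kurtosis(x)^2 / mx,
      S3 = s^2 * .raw_kurtosis(x)^2 / rng)
  }
  bad <- !is.finite(scales) | scales == 0
  if (any(bad)) {
    stop(method, " scaling produced a zero or non-finite scale for column(s): ",
         paste(colnames(x)[bad], collapse = ", "), call. = FALSE)
  }
  names(centers) <- names(scales) <- colnames(x)
  structure(list(method = method, centers = centers, scales = scales),
            class = "scaling_spec")
}

#' @export
print.scaling_spec <- function(x, ...) {
  cat("Scaling spec:", x$method, "(", length(x$scales), "columns )\n")
  print(rbind(center = x$centers, scale = x$scales))
  invisible(x)
}

#' Apply or invert a column normalization
#'
#' `normalize_data()` maps each column `j` to `(X_j - c_j)/d_j`;
#' `denormalize_data()` is its exact inverse.
#'
#' @param x Numeric matrix with the same number of columns as `spec`.
#' @param spec A `"scaling_spec"` from [scaling_spec()], or a scaling name
#'   (in which case the spec is computed from `x` itself).
#' @return Numeric matrix of the same shape, with a `"scaling_spec"` attribute
#'   on the normalized output.
#' @export
normalize_data <- function(x, spec = "Auto") {
  x <- as_data_matrix(x)
  if (is.character(spec)) spec <- scaling_spec(x, spec)
  stopifnot(inherits(spec, "scaling_spec"))
  if (length(spec$scales) != ncol(x)) {
    stop("scaling spec has ", length(spec$scales), " columns but data has ",
         ncol(x), call. = FALSE)
  }
  out <- sweep(sweep(x, 2L, spec$centers, "-"), 2L, spec$scales, "/")
  attr(out, "scaling_spec") <- spec
  out
}

#' @rdname normalize_data
#' @export
denormalize_data <- function(x, spec) {
  x <- as_data_matrix(x)
  stopifnot(inherits(spec, "scaling_spec"))
  if (length(spec$scales) != ncol(x)) {
    stop("scaling spec has ", length(spec$scales), " columns but data has ",
         ncol(x), call. = FALSE)
  }
  out <- sweep(sweep(x, 2L, spec$scales, "*"), 2L, spec$centers, "+")
  attr(out, "scaling_spec") <- NULL
  out
}

# coerce to a validated numeric matrix with unique column names
as_data_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix or data frame", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("data matrix contains non-finite entries", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("column names must be unique", call. = FALSE)
  x
}
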