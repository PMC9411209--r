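#' Toy manifolds for validating the cost function
#'
#' Each generator returns a list with `eta` (a `"manifold_params"` object),
#' `phi` (dependent-variable matrix with values in \[0, 1\] where noted) and
#' the generating parameters. Grid-based generators are deterministic;
#' sampled generators take a seed.
#'
#' @name toy_manifolds
NULL

#' Gaussian bump on a square grid
#'
#' A radial Gaussian \eqn{\phi = \exp(-(x^2+y^2)/(2s^2))} evaluated on a
#' uniform `grid_n` x `grid_n` grid over \eqn{[-extent, extent]^2} centered
#' at the origin. The default extent of 1.5 keeps even the largest study
#' bump (`s = 0.6`, 2.5 standard deviations inside the domain) a contained
#' feature rather than a domain-filling one. Increasing `s` enlarges the
#' single feature; the manifold cost should fall as `s` grows.
#'
#' @param s Gaussian standard deviation (feature size), > 0; the study range
#'   is 0.05 to 0.6.
#' @param grid_n Points per axis (default 50, >= 10).
#' @param extent Half-width of the square domain (default 1.5).
#' @return See [toy_manifolds].
#' @export
toy_gaussian_bump <- function(s, grid_n = 50, extent = 1.5) {
  stopifnot(s > 0, grid_n >= 10, extent > 0)
  ax <- seq(-extent, extent, length.out = grid_n)
  g <- expand.grid(x = ax, y = ax)
  phi <- exp(-(g$x^2 + g$y^2) / (2 * s^2))
  list(eta = manifold_params(cbind(eta1 = g$x, eta2 = g$y)),
       phi = cbind(phi = .to_unit_range(phi)),
       s = s, grid_n = grid_n)
}

#' Superposition of sine waves
#'
#' \eqn{\phi = \sum_{k=1}^{n} \sin(2^k x)} on a uniform grid of `n_points`
#' over \eqn{[0, 2\pi]}, normalized to \[0, 1\]. Each added term introduces a
#' feature at half the previous scale, so the manifold cost should rise
#' with `n_scales`.
#'
#' @param n_scales Number of superposed frequencies, 1..5.
#' @param n_points Number of x samples (default 1000).
#' @return See [toy_manifolds]; `eta` is one-dimensional.
#' @export
toy_sine_superposition <- function(n_scales, n_points = 1000) {
  stopifnot(n_scales >= 1, n_scales <= 5, n_points >= 10)
  x <- seq(0, 2 * pi, length.out = n_points)
  phi <- rowSums(sapply(seq_len(n_scales), function(k) sin(2^k * x)))
  list(eta = manifold_params(cbind(eta1 = x)),
       phi = cbind(phi = .to_unit_range(phi)),
       n_scales = n_scales, n_points = n_points)
}

#' Linear profile with controlled non-uniqueness
#'
#' `n_unique` points uniformly spaced on \eqn{x \in [0, 1]} (spacing ~ 1e-3
#' at the default resolution) carry \eqn{\phi = x}. Non-uniqueness is added
#' as `d` extra observations with \eqn{\phi = 0}, placed at the midpoints of
#' every other adjacent pair of unique points, the `d` midpoints spread
#' evenly across the whole domain so that the non-uniqueness deepens
#' uniformly with `d`. The distance from a unique point to its nearest
#' overlapping observation is half the grid spacing (~ 5e-4), which is where
#' the extra rise in the derivative curve appears.
#'
#' @param d Overlap depth: number of added overlapping observations, 0..90 in
#'   the study.
#' @param n_unique Number of unique points (default 1000).
#' @return See [toy_manifolds]; `eta` is one-dimensional.
#' @export
toy_overlap <- function(d, n_unique = 1000) {
  stopifnot(d >= 0, n_unique >= 10)
  x <- seq(0, 1, length.out = n_unique)
  # midpoints of every other adjacent pair: (x1,x2), (x3,x4), ...
  mid <- (x[seq(1L, n_unique - 1L, by = 2L)] +
          x[seq(2L, n_unique, by = 2L)]) / 2
  if (d > length(mid)) {
    stop("d = ", d, " exceeds the ", length(mid), " available midpoints",
         call. = FALSE)
  }
  sel <- if (d > 0) unique(round(seq(1, length(mid), length.out = d))) else integer()
  if (length(sel) < d) {
    stop("d = ", d, " exceeds the ", length(mid), " available midpoints",
         call. = FALSE)
  }
  xs <- c(x, mid[sel])
  phi <- c(x, rep(0, d))
  list(eta = manifold_params(cbind(eta1 = xs)),
       phi = cbind(phi = phi),
       d = d, n_unique = n_unique)
}

#' Two Gaussian class clouds
#'
#' Two isotropic 2D Gaussian clouds (unit standard deviation) whose centers
#' are `separation` apart on the first axis; the dependent variable is the
#' numeric class label (0/1). With `separation = 0` the classes overlap
#' completely and the derivative curve gains an extra low-sigma peak; with
#' well-separated clouds it shows a single rise and a lower cost.
#'
#' @param separation Distance between cloud centers, >= 0.
#' @param n_per_cloud Points per cloud (default 500, >= 10).
#' @param seed Integer seed (default 100).
#' @return See [toy_manifolds]; `phi` holds the class labels.
#' @export
toy_two_clouds <- function(separation, n_per_cloud = 500, seed = 100) {
  stopifnot(separation >= 0, n_per_cloud >= 10)
  pts <- withr_seed(seed, {
    cbind(c(rnorm(n_per_cloud), rnorm(n_per_cloud) + separation),
          rnorm(2 * n_per_cloud))
  })
  colnames(pts) <- c("eta1", "eta2")
  list(eta = manifold_params(pts),
       phi = cbind(label = rep(c(0, 1), each = n_per_cloud)),
       separation = separation, n_per_cloud = n_per_cloud, seed = seed)
}

#' Swiss roll
#'
#' The classic 3D swiss roll: \eqn{(t \cos t, h, t \sin t)} with the roll
#' parameter \eqn{t} uniform on \eqn{[1.5\pi, 4.5\pi]} and the height
#' \eqn{h} uniform on \eqn{[0, 21]}. The dependent variable is the roll
#' parameter itself, normalized to \[0, 1\].
#'
#' @param n_samples Number of points (default 1000, >= 100).
#' @param seed Integer seed (default 100).
#' @return List with `coords` (N x 3 matrix, columns x/y/z), `eta` (the same
#'   coordinates as `"manifold_params"`), `phi`, and `t` (the raw roll
#'   parameter).
#' @export
toy_swiss_roll <- function(n_samples = 1000, seed = 100) {
  stopifnot(n_samples >= 100)
  dat <- withr_seed(seed, {
    t <- runif(n_samples, 1.5 * pi, 4.5 * pi)
    h <- runif(n_samples, 0, 21)
    list(t = t, h = h)
  })
  coords <- cbind(x = dat$t * cos(dat$t), y = dat$h, z = dat$t * sin(dat$t))
  list(coords = coords,
       eta = manifold_params(coords),
       phi = cbind(phi = .to_unit_range(dat$t)),
       t = dat$t, n_samples = n_samples, seed = seed)
}

# min-max normalization to [0, 1]
.to_unit_range <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) stop("cannot unit-range a constant vector", call. = FALSE)
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Write a toy fixture as a delimited table
#'
#' Columns are the manifold coordinates followed by the dependent
#' variable(s), one observation per row.
#'
#' @param toy A generator result (see [toy_manifolds]).
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_toy <- function(toy, path, sep = "\t") {
  coords <- if (!is.null(toy$coords)) toy$coords else toy$eta$values
  df <- data.frame(coords, toy$phi, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
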