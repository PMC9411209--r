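# Independent brute-force implementations used as oracles. These deliberately
# mirror the defining formulas with explicit double loops and share no code
# with the package internals.

# normalized variance at one bandwidth, O(N^2) double loop
brute_normalized_variance <- function(eta, phi, sigma) {
  n <- nrow(eta)
  k <- numeric(n)
  for (a in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      w <- exp(-sum((eta[j, ] - eta[a, ])^2) / sigma^2)
      num <- num + w * phi[j]
      den <- den + w
    }
    k[a] <- num / den
  }
  sum((phi - k)^2) / sum((phi - mean(phi))^2)
}

# integral by midpoint Riemann sum on a linear interpolant, heavily refined
riemann_area <- function(xg, yg, refine = 200) {
  xf <- seq(xg[1], xg[length(xg)], length.out = refine * length(xg))
  yf <- approx(xg, yg, xout = xf)$y
  dx <- diff(xf)
  sum((yf[-1] + yf[-length(yf)]) / 2 * dx)
}

# small random dataset with named columns, positive values (safe for all
# scalings), reproducible
random_positive_matrix <- function(n, q, seed) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * q)), n, q) + 0.5
  colnames(m) <- paste0("v", seq_len(q))
  m
}

# short sigma grid for routine tests (full 200-point grid reserved for the
# acceptance suite)
test_grid <- function(n = 60) sigma_grid(1e-7, 1e3, n)
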