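test_that("kernel estimate reproduces closed-form two-point value and limits", {
  eta <- cbind(eta1 = c(0, 1))
  phi <- c(0, 1)
  # query at 0, sigma = 1: w = (1, e^-1) -> K = e^-1 / (1 + e^-1)
  got <- kernel_estimate(0, sigma = 1, eta, phi)
  expect_equal(unname(got[1, 1]), exp(-1) / (1 + exp(-1)), tolerance = 1e-12)

  # huge sigma: every weight ~1 -> arithmetic mean
  x20 <- matrix(runif(40), 20, 2)
  phi20 <- runif(20)
  got <- kernel_estimate(c(0.5, 0.5), sigma = 1e6, x20, phi20)
  expect_equal(unname(got[1, 1]), mean(phi20), tolerance = 1e-6)

  # brute-force double loop on a random instance
  q <- matrix(runif(10), 5, 2)
  manual <- sapply(seq_len(5), function(a) {
    w <- exp(-rowSums((x20 - matrix(q[a, ], 20, 2, byrow = TRUE))^2) / 0.3^2)
    sum(w * phi20) / sum(w)
  })
  expect_equal(unname(kernel_estimate(q, 0.3, x20, phi20)[, 1]), manual,
               tolerance = 1e-12)
})

test_that("kernel weight underflow falls back to the nearest observation", {
  eta <- cbind(eta1 = c(0, 1))
  phi <- c(3, 7)
  expect_warning(got <- kernel_estimate(100, sigma = 1e-6, eta, phi),
                 "underflow")
  expect_equal(unname(got[1, 1]), 7)
})

test_that("normalized variance attains its analytic limits", {
  toy <- toy_overlap(d = 0, n_unique = 200)
  cur <- normalized_variance(toy$eta, toy$phi, test_grid())
  nv <- cur$N[, 1]
  expect_lt(nv[1], 1e-6)                    # sigma -> 0: self-prediction
  expect_equal(nv[length(nv)], 1, tolerance = 0.02)  # sigma >> diameter
  expect_true(all(nv >= 0))

  # duplicated locations with differing phi: variance never resolves
  eta_dup <- cbind(eta1 = c(0, 0))
  phi_dup <- c(0, 1)
  cur_dup <- suppressWarnings(normalized_variance(eta_dup, phi_dup, test_grid()))
  expect_equal(unname(cur_dup$N[, 1]), rep(1, 60), tolerance = 1e-12)

  expect_error(normalized_variance(toy$eta, rep(2, 200), test_grid()),
               "constant")
})

test_that("production sweep matches the brute-force double-loop oracle", {
  set.seed(14)
  for (case in 1:2) {
    n <- c(60, 150)[case]
    qdim <- c(1, 2)[case]
    eta <- matrix(runif(n * qdim), n, qdim)
    phi <- matrix(runif(n), ncol = 1, dimnames = list(NULL, "phi"))
    sigmas <- sort(10^runif(10, -4, 2))
    curves <- normalized_variance(manifold_params(eta, unit_box_scaled = TRUE),
                                  phi, sigmas)
    oracle <- sapply(sigmas, function(s) brute_normalized_variance(eta, phi, s))
    expect_equal(unname(curves$N[, 1]), oracle, tolerance = 1e-10)
  }
})

test_that("normalized variance is affine- and permutation-invariant", {
  set.seed(31)
  eta <- matrix(runif(160), 80, 2)
  phi <- runif(80)
  g <- test_grid()
  base <- normalized_variance(eta, phi, g)$N

  shifted <- normalized_variance(eta, -2.5 * phi + 7, g)$N
  expect_equal(base, shifted, tolerance = 1e-10, ignore_attr = TRUE)

  perm <- sample(80)
  permuted <- normalized_variance(eta[perm, ], phi[perm], g)$N
  expect_equal(base, permuted, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("derivative curves normalize to unit maximum with correct limits", {
  toy <- toy_overlap(d = 0, n_unique = 200)
  cur <- variance_derivative(normalized_variance(toy$eta, toy$phi, test_grid()))
  expect_equal(max(cur$Dhat[, 1]), 1)
  expect_equal(unname(cur$limit_at_zero[[1]]), unname(cur$N[1, 1]))

  # flat N == 1 gives D == 1 (limit term only)
  cur_dup <- suppressWarnings(
    variance_derivative(normalized_variance(cbind(eta1 = c(0, 0)), c(0, 1),
                                            test_grid())))
  expect_equal(unname(cur_dup$D[, 1]), rep(1, 60), tolerance = 1e-12)
  expect_equal(unname(cur_dup$Dhat[, 1]), rep(1, 60), tolerance = 1e-12)
})

test_that("rightmost-peak detection handles plateaus, shifts and fallbacks", {
  g <- sigma_grid(1e-3, 1e2, 11)
  unimodal <- c(0, 1, 2, 5, 3, 2, 1, 0.5, 0.2, 0.1, 0)
  expect_equal(find_sigma_peak(unimodal, g)$peak_index, 4L)

  bimodal <- c(0, 3, 1, 0.5, 2, 5, 2, 1, 0.5, 0.2, 0)
  pk <- find_sigma_peak(bimodal, g)
  expect_equal(pk$peak_index, 6L)
  expect_equal(pk$peak_indices, c(2L, 6L))

  plateau <- c(0, 1, 2, 2, 2, 1, 0, 0, 0, 0, 0)
  expect_equal(find_sigma_peak(plateau, g)$peak_index, 5L)  # rightmost of plateau

  # shift moves the effective log-location right, monotonically in p
  locs <- sapply(c(0, 0.3, 0.7), function(p)
    find_sigma_peak(unimodal, g, peak_shift = p)$log_sigma_peak)
  expect_true(all(diff(locs) > 0))
  expect_equal(locs[1], g$log_values[4])

  # tiny numerical wiggles below the noise floor are not peaks
  noisy <- c(0, 1, 2, 5, 3, 2, 1, 1e-9, 2e-9, 1e-9, 0)
  expect_equal(find_sigma_peak(noisy, g)$peak_index, 4L)

  # monotone curve: no interior maximum, rightmost argmax fallback
  rising <- seq(0, 1, length.out = 11)
  expect_equal(find_sigma_peak(rising, g)$peak_index, 11L)
})

test_that("curves export as a tidy table", {
  toy <- toy_overlap(d = 0, n_unique = 100)
  cur <- variance_derivative(normalized_variance(toy$eta, toy$phi, test_grid(20)))
  tmp <- tempfile(fileext = ".tsv")
  curves_table(cur, tmp)
  back <- read.delim(tmp)
  expect_equal(names(back), c("sigma", "N_phi", "Dhat_phi"))
  expect_equal(back$N_phi, unname(cur$N[, 1]), tolerance = 1e-12)
})
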