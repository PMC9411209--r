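# One informative column plus low-variance noise columns; with no rescaling
# the PCA projection is dominated by whichever informative structure remains,
# so removal costs separate cleanly.
make_signal_noise_data <- function(n = 200, n_noise = 3, seed = 4) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n)
  noise <- matrix(rnorm(n * n_noise, 0.5, 0.1), n, n_noise)
  colnames(noise) <- paste0("n", seq_len(n_noise))
  list(x = cbind(cbind(signal = t), noise), phi = cbind(target = t))
}

test_that("backward elimination keeps the informative variable", {
  d <- make_signal_noise_data()
  opts <- cost_options(grid = test_grid(40))
  tr <- select_features(d$x, d$phi, q = 2, scaling = "None", options = opts)

  expect_s3_class(tr, "feature_selection")
  # Q - q = 2 elimination iterations plus the recorded full set
  expect_equal(tr$iterations$iteration, 0:2)
  expect_true(is.na(tr$iterations$removed[1]))
  # the signal column is never the minimizing removal while noise remains
  expect_false("signal" %in% tr$iterations$removed[2:3])
  expect_true("signal" %in% tr$optimal_subset)
  # bookkeeping: returned cost is the minimum over the trace
  expect_equal(tr$optimal_cost, min(tr$iterations$cost))
  expect_lte(tr$optimal_cost, tr$iterations$cost[1])
  expect_gte(length(tr$optimal_subset), 2)
})

test_that("elimination trace is deterministic and exhaustive per iteration", {
  d <- make_signal_noise_data(n = 120, seed = 12)
  opts <- cost_options(grid = test_grid(30))
  tr1 <- select_features(d$x, d$phi, q = 3, scaling = "None", options = opts)
  tr2 <- select_features(d$x, d$phi, q = 3, scaling = "None", options = opts)
  expect_identical(tr1$iterations, tr2$iterations)

  # iteration 1 cost equals the best over all single-removal candidates,
  # evaluated independently
  cand <- sapply(colnames(d$x), function(cn) {
    manifoldcost:::subset_projection_cost(d$x, setdiff(colnames(d$x), cn),
                                          d$phi, 3, "None", opts)
  })
  expect_equal(tr1$iterations$cost[2], min(cand), tolerance = 1e-12)
  expect_equal(tr1$iterations$removed[2], names(which.min(cand)))
})

test_that("q = Q returns the full set untouched; q > Q errors", {
  d <- make_signal_noise_data(n = 80, seed = 6)
  opts <- cost_options(grid = test_grid(25))
  tr <- select_features(d$x, d$phi, q = 4, scaling = "None", options = opts)
  expect_equal(nrow(tr$iterations), 1L)
  expect_equal(tr$best_iteration, 0L)
  expect_setequal(tr$optimal_subset, colnames(d$x))
  expect_error(select_features(d$x, d$phi, q = 5, options = opts), "exceed")
})

test_that("scaling rankings place variance-aware scalings above None for dominant-range data", {
  set.seed(23)
  n <- 120
  t <- seq(0, 1, length.out = n)
  x <- cbind(signal = t, bulk = rlnorm(n, 5, 1))  # bulk range dwarfs signal
  rk <- rank_scalings(x, cbind(target = t), q = 1,
                      methods = c("None", "Auto", "VAST"),
                      options = cost_options(grid = test_grid(40)))
  expect_equal(names(rk), c("scaling", "cost"))
  expect_lt(rk$cost[rk$scaling == "Auto"], rk$cost[rk$scaling == "None"])
  expect_lt(rk$cost[rk$scaling == "VAST"], rk$cost[rk$scaling == "None"])
  expect_true(!is.unsorted(rk$cost))
})

test_that("selection trace round-trips through its writers", {
  d <- make_signal_noise_data(n = 80, seed = 2)
  tr <- select_features(d$x, d$phi, q = 3, scaling = "None",
                        options = cost_options(grid = test_grid(25)))
  prefix <- tempfile()
  write_feature_selection(tr, prefix)
  back <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(unlist(back$optimal_subset), tr$optimal_subset,
               ignore_attr = TRUE)
  tsv <- read.delim(paste0(prefix, ".tsv"))
  expect_equal(tsv$cost, tr$iterations$cost, tolerance = 1e-12)
})
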