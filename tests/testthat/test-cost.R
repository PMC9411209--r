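test_that("penalty curve matches closed-form values", {
  g <- sigma_grid(1e-7, 1e3, 201)
  # peak at sigma = 1 (log10 = 0), r = b = 1: P(peak) = 10/7
  p <- penalty_curve(g, log_sigma_peak = 0, r = 1, b = 1)
  i0 <- which.min(abs(g$log_values))
  expect_equal(p[i0], 10 / 7, tolerance = 1e-12)
  expect_equal(p, abs(g$log_values)^1 + 10 / 7, tolerance = 1e-12)

  # distance term strictly increases away from the peak
  left <- p[seq_len(i0 - 1)]
  right <- p[seq(i0 + 1, length(p))]
  expect_true(all(diff(left) < 0) && all(diff(right) > 0))

  expect_error(penalty_curve(g, log_sigma_peak = -7), "degenerate peak")
})

test_that("areas and costs agree with closed forms and a refinement oracle", {
  g <- sigma_grid(1e-7, 1e3, 200)
  ones <- rep(1, 200)
  expect_equal(curve_area(ones, g), 10, tolerance = 1e-12)
  expect_equal(curve_area(rep(0, 200), g), 0)

  # D == 1 on [-7,3], peak at the top (log10 = 3), r = b = 1:
  # integral of (|s-3| + 1) ds = 50 + 10 = 60
  expect_equal(cost_variable(ones, g, log_sigma_peak = 3), 60, tolerance = 0.005 * 60)

  set.seed(5)
  rough <- abs(sin(g$log_values)) * exp(-((g$log_values + 2) / 3)^2)
  expect_equal(curve_area(rough, g), riemann_area(g$log_values, rough),
               tolerance = 1e-3)

  # b = 0 with all mass at the peak: penalty vanishes there
  spike <- numeric(200); spike[120] <- 1
  L <- cost_variable(spike, g, g$log_values[120],
                     cost_options(b = 0, grid = g))
  expect_lt(L, 0.01)
})

test_that("aggregate norms behave as stated", {
  expect_equal(aggregate_cost(c(1.0, 1.8), "L1"), 2.8)
  expect_equal(aggregate_cost(c(3, 4), "L2"), 5)
  expect_equal(aggregate_cost(c(3, 4), "max"), 4)
  expect_equal(aggregate_cost(1.7, "L1"), aggregate_cost(1.7, "L2"))
  expect_error(aggregate_cost(numeric(0)), "no per-variable")
})

test_that("assess_manifold is invariant to affine phi, row and column permutations", {
  set.seed(19)
  eta <- matrix(runif(240), 120, 2)
  phi <- cbind(a = runif(120), b = runif(120))
  opts <- cost_options(grid = test_grid())
  base <- assess_manifold(eta, phi, opts)

  aff <- assess_manifold(eta, cbind(a = 3 * phi[, 1] - 1, b = -0.5 * phi[, 2] + 2), opts)
  expect_equal(base$cost, aff$cost, tolerance = 1e-10)

  perm <- sample(120)
  rowp <- assess_manifold(eta[perm, ], phi[perm, ], opts)
  expect_equal(base$cost, rowp$cost, tolerance = 1e-10)

  colp <- assess_manifold(eta[, 2:1], phi, opts)
  expect_equal(base$cost, colp$cost, tolerance = 1e-10)

  expect_equal(base$cost, aggregate_cost(base$variables$cost, "L1"))
})

test_that("overlapping class clouds cost more than separated ones", {
  opts <- cost_options(grid = test_grid())
  over <- toy_two_clouds(separation = 0, n_per_cloud = 150)
  apart <- toy_two_clouds(separation = 10, n_per_cloud = 150)
  L_over <- assess_manifold(over$eta, over$phi, opts)$cost
  L_apart <- assess_manifold(apart$eta, apart$phi, opts)$cost
  expect_gt(L_over, L_apart)
})

test_that("cost report serializes with provenance", {
  toy <- toy_overlap(d = 10, n_unique = 150)
  rep <- assess_manifold(toy$eta, toy$phi, cost_options(grid = test_grid(30)))
  tmp <- tempfile(fileext = ".json")
  write_cost_report(rep, tmp, provenance = list(seed = 100, input = "toy"))
  back <- jsonlite::read_json(tmp)
  expect_equal(back$aggregate_cost, rep$cost, tolerance = 1e-12)
  expect_equal(back$options$r, 1)
  expect_equal(back$provenance$seed, 100)
  expect_equal(back$per_variable[[1]]$name, "phi")
})
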