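test_that("the profile attains the global optimum at the estimate", {
  pb <- const_problem(b = c(p1 = 0.4), sigma = 0.1)
  fit <- fit_ml(pb, n_starts = 1, seed = 1)
  pr <- profile_likelihood(pb, fit, "r_p1")
  expect_equal(min(pr$grid$chi2), fit$value, tolerance = 1e-8)
  # the profile never beats the global optimum
  expect_true(all(pr$grid$chi2 >= pr$chi2_min - 1e-8))
  # and the interval contains the estimate
  expect_lte(pr$ci$lower, pr$estimate)
  expect_gte(pr$ci$upper, pr$estimate)
})

test_that("profiles match the closed-form conditional quadratic", {
  # y0 = 0 and y1 = b measured with sd sigma share the reference
  # parameter: profiling the fold-change gives the Schur-complement
  # curvature 1/(2 sigma^2), i.e. chi2_PL(r) = (r - b)^2 / (2 sigma^2)
  sigma <- 0.1
  b <- 0.4
  pb <- const_problem(b = c(p1 = b), sigma = sigma)
  fit <- fit_ml(pb, n_starts = 1, seed = 1)
  grid <- seq(b - 0.5, b + 0.5, length.out = 21)
  pr <- profile_likelihood(pb, fit, "r_p1", grid = grid)
  on_grid <- pr$grid[pr$grid$value %in% grid, ]
  expect_equal(on_grid$chi2, (on_grid$value - b)^2 / (2 * sigma^2),
               tolerance = 1e-6)
})

test_that("independent parameters give profiles equal to 1-D slices", {
  pb <- const_problem(b = c(p1 = 0.3, p2 = -0.2), sigma = 0.1)
  fit <- fit_ml(pb, n_starts = 1, seed = 1)
  grid <- seq(-0.1, 0.7, length.out = 9)
  pr <- profile_likelihood(pb, fit, "r_p1", grid = grid)
  slice <- vapply(grid, function(v) {
    r <- fit$r
    r[["p1"]] <- v
    # block-diagonal problem: re-optimization leaves the other block at
    # its optimum, and p0_1 re-optimizes to (y0 + y1 - r)/2
    lp <- fit$log_p0
    lp[["p1"]] <- (0 + (0.3 - v)) / 2 + 0  # conditional optimum
    chi2_ml(pb, lp, r)$value
  }, numeric(1))
  on_grid <- pr$grid[pr$grid$value %in% grid, ]
  expect_equal(on_grid$chi2, slice, tolerance = 1e-6)
})

test_that("confidence intervals follow normal theory on a Gaussian profile", {
  # chi2_PL(r) = (r - b)^2 / (2 sigma^2): the 95% interval has
  # half-width 1.96 * sqrt(2) * sigma
  sigma <- 0.1
  b <- 0.4
  pb <- const_problem(b = c(p1 = b), sigma = sigma)
  fit <- fit_ml(pb, n_starts = 1, seed = 1)
  pr <- profile_likelihood(pb, fit, "r_p1", alpha = 0.95)
  halfwidth <- sqrt(chi2_quantile(0.95, 1) * 2 * sigma^2)
  expect_equal(pr$ci$upper - pr$estimate, halfwidth, tolerance = 1e-2)
  expect_equal(pr$estimate - pr$ci$lower, halfwidth, tolerance = 1e-2)
  expect_false(pr$ci$lower_open)
  expect_false(pr$ci$upper_open)
})

test_that("a flat direction yields an open interval", {
  # an unused parameter never changes the objective: the threshold is
  # never crossed inside the bounds (practical non-identifiability)
  model <- ode_model(state_names = "x", param_names = c("k", "ghost"),
                     rhs = function(t, x, p) -p[["k"]] * x, x0 = 1)
  times <- seq(0, 3, length.out = 7)
  tr <- simulate_model(model, c(k = 0, ghost = 0), times)
  meas <- tibble::tibble(observableId = "x", conditionId = "base",
                         cellType = 0L, time = times,
                         measurement = tr$states[, "x"], sd = 0.05)
  pb <- fc_problem(model, meas, list(base = condition("base")),
                   penalized = character())
  fit <- foldreg:::fit_unpenalized(pb, starts = matrix(c(0, 0), nrow = 1))
  pr <- profile_likelihood(pb, fit, "ghost",
                           control = list(max_steps = 20L))
  expect_true(pr$ci$lower_open || pr$ci$upper_open)
})

test_that("fold-changes compatible with zero are flagged by their interval", {
  # a weak fold-change whose interval straddles zero: candidate for
  # manual removal after regularization
  pb <- const_problem(b = c(p1 = 0.05), sigma = 0.1)
  fit <- fit_ml(pb, n_starts = 1, seed = 1)
  pr <- profile_likelihood(pb, fit, "r_p1")
  expect_true(pr$ci$lower < 0 && pr$ci$upper > 0)
})

test_that("the 2-D profile grid reproduces the additive structure", {
  pb <- const_problem(b = c(p1 = 0.3, p2 = -0.2), sigma = 0.1)
  fit <- fit_ml(pb, n_starts = 1, seed = 1)
  g1 <- c(0.1, 0.3, 0.5)
  g2 <- c(-0.4, -0.2, 0)
  land <- profile_likelihood_2d(pb, fit, c("r_p1", "r_p2"), g1, g2)
  expect_equal(nrow(land), 9)
  # independent blocks: chi2 adds across the two coordinates
  a <- 1 / (2 * 0.1^2)
  expect_equal(land$chi2,
               a * (land$v1 - 0.3)^2 + a * (land$v2 + 0.2)^2,
               tolerance = 1e-4)
})
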