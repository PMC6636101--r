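test_that("cell-type mapping adds fold-changes on the log scale", {
  lp <- c(a = 0, b = 1, c = -2)
  r <- c(a = 0.5, b = 0)
  expect_identical(map_celltype_params(lp, r, 0L), lp)
  m1 <- map_celltype_params(lp, r, 1L)
  expect_equal(m1, c(a = 0.5, b = 1, c = -2))
  # a 10-fold change moves a unit parameter to log10 p = 1
  expect_equal(map_celltype_params(c(p = 0), c(p = log10(10)), 1L)[["p"]], 1)
  # round trip: the fold-change is recovered from the two cell types
  expect_equal(10^(m1 - lp)[["a"]], 10^0.5)
  expect_error(map_celltype_params(lp, c(zz = 1), 1L), "unknown")
})

test_that("chi2 equals the direct double-loop summation", {
  pb <- decay2_problem()
  lp <- c(k = 0.1, a = -0.05)
  r <- c(k = 0.2, a = 0)
  got <- chi2_ml(pb, lp, r)
  # oracle: loop over every record, simulate, square, sum
  total <- 0
  for (i in seq_len(nrow(pb$measurements))) {
    row <- pb$measurements[i, ]
    lpi <- if (row$cellType == 1) lp + r[names(lp)] else lp
    tr <- simulate_model(pb$model, lpi, times = row$time)
    total <- total + ((row$measurement - unname(tr$states[1, "x"])) /
                        row$sd)^2
  }
  # per-record integrations take different adaptive steps than the
  # grouped integration, so agreement is to solver tolerance
  expect_equal(got$value, total, tolerance = 1e-6)
})

test_that("chi2 has the expected simple values", {
  # perfect fit: zero
  pb <- decay2_problem(r_true = c(k = 0, a = 0))
  expect_equal(chi2_ml(pb, c(k = 0, a = 0), c(k = 0, a = 0))$value, 0,
               tolerance = 1e-12)
  # a single residual of 2 with unit sd contributes 4
  pb1 <- const_problem(b = 0, sigma = 1)
  m <- pb1$measurements
  m$measurement[1] <- m$measurement[1] + 2
  pb1 <- fc_problem(pb1$model, m, pb1$conditions)
  expect_equal(chi2_ml(pb1, c(p1 = 0), c(p1 = 0))$value, 4, tolerance = 1e-10)
})

test_that("chi2 is invariant to the order of measurement records", {
  pb <- decay2_problem()
  set.seed(7)
  shuffled <- pb$measurements[sample(nrow(pb$measurements)), ]
  pb2 <- fc_problem(pb$model, shuffled, pb$conditions,
                    penalized = pb$penalized)
  lp <- c(k = 0.2, a = 0.1)
  expect_equal(chi2_ml(pb, lp)$value, chi2_ml(pb2, lp)$value,
               tolerance = 1e-12)
})

test_that("chi2 gradient matches central finite differences", {
  pb <- decay2_problem()
  set.seed(11)
  for (rep in 1:3) {
    lp <- c(k = runif(1, -0.3, 0.3), a = runif(1, -0.3, 0.3))
    r <- c(k = runif(1, -0.3, 0.3), a = runif(1, -0.3, 0.3))
    cc <- chi2_ml(pb, lp, r, gradient = TRUE)
    h <- 1e-5
    for (pn in names(lp)) {
      hi <- lp; hi[pn] <- hi[pn] + h
      lo <- lp; lo[pn] <- lo[pn] - h
      fd <- (chi2_ml(pb, hi, r)$value - chi2_ml(pb, lo, r)$value) / (2 * h)
      expect_equal(cc$grad_p0[[pn]], fd, tolerance = 1e-3)
      hi <- r; hi[pn] <- hi[pn] + h
      lo <- r; lo[pn] <- lo[pn] - h
      fd <- (chi2_ml(pb, lp, hi)$value - chi2_ml(pb, lp, lo)$value) / (2 * h)
      expect_equal(cc$grad_r[[pn]], fd, tolerance = 1e-3)
    }
  }
})

test_that("the compiled whole-objective path equals the generic evaluation", {
  run <- make_benchmark_run(77, n_genes = 3)
  pb <- benchmark_problem(run)
  expect_false(is.null(pb$fastplan))
  ref <- attr(run$model, "reference_log10")
  set.seed(3)
  r <- stats::setNames(runif(length(pb$penalized), -0.2, 0.2), pb$penalized)
  fast <- chi2_ml(pb, ref, r, gradient = TRUE)
  generic <- pb
  generic$fastplan <- NULL
  slow <- chi2_ml(generic, ref, r, gradient = TRUE)
  expect_equal(fast$value, slow$value, tolerance = 1e-9)
  expect_equal(fast$grad_p0, slow$grad_p0, tolerance = 1e-8)
  expect_equal(fast$grad_r, slow$grad_r, tolerance = 1e-8)
})

test_that("multi-start optimization solves a quadratic exactly", {
  fn <- function(x) (x[1] - 1)^2 + 2 * (x[2] + 2)^2
  gr <- function(x) c(2 * (x[1] - 1), 4 * (x[2] + 2))
  starts <- foldreg:::lhs_starts(5, c(-5, -5), c(5, 5), seed = 1)
  best <- foldreg:::multistart_optim(starts, fn, gr, c(-5, -5), c(5, 5))
  expect_equal(unname(best$par), c(1, -2), tolerance = 1e-6)
  expect_equal(best$value, 0, tolerance = 1e-10)
})

test_that("noise-free data are refit to the generating parameters", {
  pb <- decay2_problem(r_true = c(k = 0.4, a = 0))
  fit <- foldreg:::fit_unpenalized(pb, starts = matrix(c(0, 0, 0.4, 0),
                                                       nrow = 1))
  expect_lt(fit$value, 1e-6)
  expect_equal(unname(fit$log_p0), c(0, 0), tolerance = 1e-4)
  expect_equal(unname(fit$r), c(0.4, 0), tolerance = 1e-4)
})

test_that("the fitted optimum matches a dense grid-search oracle", {
  # two-parameter decay model, no fold-changes: compare the optimizer
  # against brute force over a 101 x 101 grid
  model <- decay2_model()
  times <- seq(0, 4, length.out = 9)
  truth <- c(k = 0.15, a = -0.1)
  tr <- simulate_model(model, truth, times)
  meas <- tibble::tibble(observableId = "x", conditionId = "base",
                         cellType = 0L, time = times,
                         measurement = tr$states[, "x"], sd = 0.05)
  pb <- fc_problem(model, meas, list(base = condition("base")),
                   penalized = character())
  grid <- seq(-1, 1, length.out = 101)
  gridval <- outer(grid, grid, Vectorize(function(k, a)
    chi2_ml(pb, c(k = k, a = a))$value))
  gmin <- which(gridval == min(gridval), arr.ind = TRUE)[1, ]
  fit <- fit_ml(pb, n_starts = 5, seed = 2)
  # same basin and at least as good as the best grid point
  expect_lt(abs(fit$log_p0[["k"]] - grid[gmin[1]]), 0.03)
  expect_lt(abs(fit$log_p0[["a"]] - grid[gmin[2]]), 0.03)
  expect_lte(fit$value, min(gridval) + 1e-6)
})

test_that("measurement validation pinpoints bad rows", {
  pb <- const_problem(b = 0.5)
  m <- pb$measurements
  m$observableId[2] <- "nope"
  expect_error(fc_problem(pb$model, m, pb$conditions), "row 2.*nope")
  m <- pb$measurements
  m$sd[2] <- -1
  expect_error(fc_problem(pb$model, m, pb$conditions), "row 2.*sd")
})
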