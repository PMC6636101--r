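test_that("penalty closed forms evaluate correctly", {
  expect_equal(penalty_value(penalty_spec("l1"), c(1, -2)), 3)
  expect_equal(penalty_value(penalty_spec("lq", deformation = 0.5), 4), 2)
  expect_equal(penalty_value(penalty_spec("elastic_net", deformation = 0.5), 2),
               0.5 * 2 + 0.5 * 4)
  al <- penalty_spec("adaptive_lasso", deformation = 1,
                     weights = adaptive_weights(c(r1 = 2), gamma = 1))
  expect_equal(penalty_value(al, c(r1 = 1)), 0.5)
  expect_error(penalty_value(penalty_spec("adaptive_lasso", 1), 1),
               "weights")
})

test_that("penalty gradients use their closed forms and the lq clamp", {
  expect_equal(unclass(penalty_gradient(penalty_spec("l1"), -3))[1], -1)
  en <- penalty_gradient(penalty_spec("elastic_net", deformation = 0.25), 2)
  expect_equal(unclass(en)[1], 0.75 + 1)
  # inside the cut-off the lq gradient is clamped to q eps^(q-1), which
  # stays finite: 0.5 * (1e-10)^(-0.5) = 5e4
  lq <- penalty_spec("lq", deformation = 0.5, epsilon = 1e-10)
  g <- penalty_gradient(lq, 1e-12)
  expect_equal(unclass(g)[1], 5e4)
  expect_true(is.finite(unclass(g)[1]))
  # outside the cut-off, the exact power law
  g2 <- penalty_gradient(lq, 0.25)
  expect_equal(unclass(g2)[1], 0.5 * 0.25^(-0.5))
  # the entry exactly at the target is flagged
  g3 <- penalty_gradient(penalty_spec("l1"), c(0, 1))
  expect_identical(attr(g3, "at_target"), c(TRUE, FALSE))
})

test_that("every family reduces to l1 at zero deformation", {
  set.seed(5)
  for (i in 1:10) {
    r <- runif(6, -3, 3)
    v1 <- penalty_value(penalty_spec("l1"), r)
    expect_equal(penalty_value(penalty_spec("lq", 0), r), v1)
    expect_equal(penalty_value(penalty_spec("elastic_net", 0), r), v1)
    al0 <- penalty_spec("adaptive_lasso", 0,
                        weights = rep(1, 6))
    expect_equal(penalty_value(al0, r), v1)
  }
})

test_that("elastic net at full elasticity is the squared l2 penalty", {
  set.seed(6)
  r <- runif(5, -2, 2)
  expect_equal(penalty_value(penalty_spec("elastic_net", 1), r), sum(r^2))
})

test_that("penalties are nonnegative and vanish at the target", {
  set.seed(8)
  for (spec in list(penalty_spec("l1", target = 0.7),
                    penalty_spec("lq", 0.3, target = -0.2),
                    penalty_spec("elastic_net", 0.4, target = 0.1))) {
    expect_equal(penalty_value(spec, rep(spec$target, 4)), 0)
    for (i in 1:5) expect_gte(penalty_value(spec, runif(4, -3, 3)), 0)
  }
})

test_that("penalty gradients match finite differences away from zero", {
  set.seed(9)
  specs <- list(penalty_spec("l1"),
                penalty_spec("lq", 0.2),
                penalty_spec("elastic_net", 0.3),
                penalty_spec("adaptive_lasso", 0.5,
                             weights = c(2, 0.5, 1.3)))
  for (spec in specs) {
    r <- c(0.8, -1.4, 2.2)
    g <- unclass(penalty_gradient(spec, r))
    h <- 1e-7
    for (i in seq_along(r)) {
      hi <- r; hi[i] <- hi[i] + h
      lo <- r; lo[i] <- lo[i] - h
      fd <- (penalty_value(spec, hi) - penalty_value(spec, lo)) / (2 * h)
      expect_equal(g[i], fd, tolerance = 1e-6)
    }
  }
})

test_that("subgradient intervals are the penalty slope times lambda", {
  expect_equal(subgradient_interval(penalty_spec("l1"), 2, c(a = 0), 1),
               c(-2, 2))
  al <- penalty_spec("adaptive_lasso", 1, weights = c(a = 4))
  expect_equal(subgradient_interval(al, 1, c(a = 0), 1), c(-4, 4))
  # lq: q eps^(q-1) evaluated numerically: 0.8 * (1e-10)^(-0.2) = 80
  lq <- penalty_spec("lq", deformation = 0.2, epsilon = 1e-10)
  expect_equal(subgradient_interval(lq, 1, c(a = 0), 1), c(-80, 80),
               tolerance = 1e-10)
  expect_error(subgradient_interval(penalty_spec("l1"), 1, c(a = 0.5), 1),
               "zero")
})

test_that("the penalized minimizer equals the analytic soft threshold", {
  # quadratic objective a (r - b)^2 with a = 1/(2 sigma^2): the l1
  # solution is sign(b) max(0, |b| - lambda / (2a))
  sigma <- 0.1
  b <- 0.6
  pb <- const_problem(b = b, sigma = sigma)
  a <- 1 / (2 * sigma^2)
  f0 <- fit_ml(pb, n_starts = 1, seed = 1)
  for (lam in c(5, 20, a * b * 2 * 0.9, a * b * 2 * 1.2)) {
    fit <- foldreg:::fit_penalized(pb, penalty_spec("l1"), lam, f0)
    expect_equal(unname(fit$r), sign(b) * max(0, abs(b) - lam / (2 * a)),
                 tolerance = 1e-4)
  }
})

test_that("optimality report applies the subgradient criteria", {
  sigma <- 0.1
  b <- 0.6
  a <- 1 / (2 * sigma^2)
  pb <- const_problem(b = b, sigma = sigma)
  f0 <- fit_ml(pb, n_starts = 1, seed = 1)
  # lambda = 0: plain gradient test at the unpenalized optimum
  rep0 <- check_optimality(pb, f0, penalty_spec("l1"), 0)
  expect_true(all(rep0$satisfied))
  # r = 0 is optimal iff lambda >= 2 a b: check both sides
  lam_hi <- 2 * a * b * 1.1
  fit_hi <- foldreg:::fit_penalized(pb, penalty_spec("l1"), lam_hi, f0)
  rep_hi <- check_optimality(pb, fit_hi, penalty_spec("l1"), lam_hi)
  expect_true(all(rep_hi$satisfied))
  expect_true(all(abs(fit_hi$r) <= 1e-10))
  lam_lo <- 2 * a * b * 0.5
  fit_lo <- foldreg:::fit_penalized(pb, penalty_spec("l1"), lam_lo, f0)
  expect_gt(abs(fit_lo$r[[1]]), 1e-10)
  rep_lo <- check_optimality(pb, fit_lo, penalty_spec("l1"), lam_lo,
                             tol = 1e-2)
  expect_true(all(rep_lo$satisfied))
  # and a fit forced to zero under the small lambda violates Eq-22-style
  # optimality: the likelihood gradient escapes the subgradient interval
  forced <- fit_lo
  forced$r[] <- 0
  rep_bad <- check_optimality(pb, forced, penalty_spec("l1"), lam_lo)
  expect_false(all(rep_bad$satisfied[rep_bad$block == "fold_change"]))
})

test_that("the clamped lq gradient does not trap the optimizer at zero", {
  # strong signal with q = 0.8: the likelihood gradient at zero
  # (2ab = 100) beats the clamped penalty slope (q eps^(q-1) = 80), so
  # the zero point is not even a local optimum and the optimizer must
  # escape it when started there
  pb <- const_problem(b = 1, sigma = 0.1)
  f0 <- fit_ml(pb, n_starts = 1, seed = 1)
  spec <- penalty_spec("lq", deformation = 0.2)
  start_zero <- list(log_p0 = f0$log_p0,
                     r = stats::setNames(1e-12, names(f0$r)))
  fit <- foldreg:::fit_penalized(pb, spec, 1, start_zero)
  expect_gt(abs(fit$r[[1]]), 0.5)
  # with a dominant penalty (lambda large) the same start stays at zero
  fit2 <- foldreg:::fit_penalized(pb, spec, 1e4, start_zero)
  expect_lte(abs(fit2$r[[1]]), 1e-10)
})

test_that("invalid penalty configurations are rejected", {
  expect_error(penalty_spec("lq", deformation = 1.1), "q")
  expect_error(penalty_spec("l1", deformation = 0.5), "deformation")
  expect_error(penalty_spec("elastic_net", deformation = 2), "alpha")
  expect_error(penalty_spec("adaptive_lasso", deformation = -1), "gamma")
})
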