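test_that("zero set uses a closed boundary at the cut-off", {
  expect_equal(zero_set(c(0, 0.5, 1e-12), 1e-10), c(1, 3))
  expect_equal(zero_set(c(a = 0, b = 0.5, c = 1e-12), 1e-10), c("a", "c"))
  expect_equal(zero_set(c(5, 7)), integer(0))
  expect_equal(zero_set(c(1e-10, -1e-10), 1e-10), c(1, 2))
})

test_that("chi-square quantiles match the standard table", {
  expect_equal(chi2_quantile(0.95, 1), 3.84, tolerance = 1e-3)
  expect_equal(chi2_quantile(0.95, 2), 5.99, tolerance = 1e-3)
  # monotone in both arguments
  expect_true(all(diff(sapply(1:10, chi2_quantile, alpha = 0.95)) > 0))
  expect_true(all(diff(sapply(c(0.5, 0.8, 0.95, 0.99), chi2_quantile,
                              m = 3)) > 0))
  expect_error(chi2_quantile(1.2, 1))
})

test_that("the likelihood-ratio statistic clamps optimizer noise", {
  expect_equal(lrt_statistic(100, 100), 0)
  expect_equal(lrt_statistic(105.3, 100), 5.3)
  expect_equal(lrt_statistic(99.999, 100), 0)          # silent clamp
  expect_warning(d <- lrt_statistic(99, 100), "baseline")
  expect_equal(d, 0)
})

test_that("restricted refits match the analytic restricted optimum", {
  # quadratic problem: forcing one fold-change to zero leaves the
  # closed-form restricted residual sum a b^2 with a = 1/(2 sigma^2)
  sigma <- 0.1
  b <- c(p1 = 0.6, p2 = -0.4)
  pb <- const_problem(b = b, sigma = sigma)
  refit <- foldreg:::fit_unpenalized(
    pb, mask = "p1", starts = matrix(c(0, 0, b[["p2"]]), nrow = 1))
  expect_equal(refit$value, b[["p1"]]^2 / (2 * sigma^2), tolerance = 1e-6)
  expect_equal(refit$r[["p1"]], 0)
})

# Build a synthetic path object for selection-rule tests.
fake_path <- function(D, n_zero, lambda = 10^seq_along(D)) {
  refits <- lapply(seq_along(D), function(k) {
    r <- stats::setNames(rep(0.5, 4), paste0("p", 1:4))
    if (n_zero[k] > 0) r[seq_len(n_zero[k])] <- 0
    structure(list(r = r, log_p0 = c(q = 0), value = 100 + D[k],
                   mask = character()), class = "fr_fit")
  })
  path <- tibble::tibble(lambda = lambda, ok = TRUE,
                         zero = lapply(refits, function(f) zero_set(f$r)),
                         n_zero = n_zero, chi2 = 100 + D, D = D,
                         refit = refits)
  structure(list(path = path, chi2_0 = 100,
                 fit0 = refits[[1]],
                 spec = penalty_spec("l1"), alpha = 0.95),
            class = "fr_regpath")
}

test_that("parsimonious selection takes the largest admissible strength", {
  # thresholds: q_0.95^(1) = 3.84, q_0.95^(2) = 5.99
  p <- fake_path(D = c(0, 1, 2, 10), n_zero = c(0, 1, 1, 2))
  sel <- parsimonious_lambda(p, 0.95)
  expect_equal(sel$lambda_star, p$path$lambda[3])
  expect_equal(length(sel$zero), 1)
})

test_that("selection is a maximum, not a first crossing", {
  # an admissible strength after an inadmissible one still wins
  p <- fake_path(D = c(0, 10, 2), n_zero = c(0, 2, 1))
  sel <- parsimonious_lambda(p, 0.95)
  expect_equal(sel$lambda_star, p$path$lambda[3])
})

test_that("an empty admissible set falls back to the unpenalized model", {
  p <- fake_path(D = c(10, 20), n_zero = c(1, 2))
  p$path$ok <- c(TRUE, TRUE)
  p$fit0 <- structure(list(r = c(p1 = 0.5), log_p0 = c(q = 0), value = 100,
                           mask = character()), class = "fr_fit")
  expect_warning(sel <- parsimonious_lambda(p, 0.95), "admissible")
  expect_equal(sel$lambda_star, 0)
})

test_that("l1 path zero patterns match the penalized-quadratic oracle", {
  # two independent fold-changes, quadratic objective with known
  # curvature: enumerate sign patterns of the penalized quadratic to
  # get the exact zero pattern per lambda
  sigma <- 0.1
  b <- c(p1 = 0.8, p2 = -0.25)
  a <- 1 / (2 * sigma^2)
  pb <- const_problem(b = b, sigma = sigma)
  f0 <- fit_ml(pb, n_starts = 1, seed = 1)
  grid <- 10^seq(-1, 3, length.out = 9)
  sc <- scan_lambda(pb, penalty_spec("l1"), grid, seed = 1, init_fit = f0)

  oracle_pattern <- function(lam) {
    # minimize sum_i a (r_i - b_i)^2 + lam |r_i| by enumerating sign
    # patterns per coordinate
    vapply(b, function(bi) {
      best <- c(value = a * bi^2, r = 0)       # pattern s = 0
      for (s in c(-1, 1)) {
        ri <- bi - s * lam / (2 * a)
        if (sign(ri) == s) {
          v <- a * (ri - bi)^2 + lam * abs(ri)
          if (v < best["value"]) best <- c(value = v, r = ri)
        }
      }
      abs(best[["r"]]) <= 1e-10
    }, logical(1))
  }
  for (k in seq_along(grid)) {
    expect_equal(sort(sc$path$zero[[k]]),
                 sort(names(b)[oracle_pattern(grid[k])]),
                 info = paste("lambda =", grid[k]))
  }
})

test_that("scan invariants hold on an exact quadratic problem", {
  sigma <- 0.1
  pb <- const_problem(b = c(p1 = 0.5, p2 = 0.02), sigma = sigma)
  f0 <- fit_ml(pb, n_starts = 1, seed = 1)
  grid <- 10^seq(-2, 3, length.out = 11)
  sc <- scan_lambda(pb, penalty_spec("l1"), grid, seed = 1, init_fit = f0)
  # the smallest lambda reproduces the unpenalized fit
  expect_equal(sc$path$chi2[1], f0$value, tolerance = 1e-6)
  expect_equal(sc$path$n_zero[1], 0)
  # D never goes negative and a large lambda shrinks everything
  expect_true(all(sc$path$D >= 0))
  expect_equal(sc$path$n_zero[length(grid)], 2)
  # final estimates come from an unpenalized refit: re-evaluating the
  # objective at them reproduces chi2(lambda*) exactly
  fin <- sc$final_fit
  expect_equal(chi2_ml(pb, fin$log_p0, fin$r)$value,
               sc$path$chi2[match(sc$lambda_star, sc$path$lambda)],
               tolerance = 1e-10)
})

test_that("parsimonious pattern agrees with exhaustive mask enumeration", {
  # noise-free two-fold-change ODE toy with one strong true difference:
  # brute force over all 2^n masks, refit each without penalty, keep the
  # sparsest admissible pattern
  pb <- decay2_problem(r_true = c(k = 0.8, a = 0), sigma = 0.05)
  f0 <- fit_ml(pb, seed = 3)
  alpha <- 0.95
  masks <- list(character(), "k", "a", c("k", "a"))
  chi2m <- vapply(masks, function(mk) {
    st <- matrix(c(f0$log_p0, f0$r[setdiff(pb$penalized, mk)]), nrow = 1)
    foldreg:::fit_unpenalized(pb, mask = mk, starts = st)$value
  }, numeric(1))
  chi2_0 <- min(chi2m)
  adm <- vapply(seq_along(masks), function(i) {
    nz <- length(masks[[i]])
    nz == 0 || chi2m[i] - chi2_0 < chi2_quantile(alpha, nz)
  }, logical(1))
  sizes <- lengths(masks)
  sparsest <- sizes[adm] == max(sizes[adm])
  oracle_patterns <- lapply(which(adm)[sparsest], function(i) sort(masks[[i]]))

  sc <- scan_lambda(pb, penalty_spec("l1"), 10^seq(-2, 4, length.out = 13),
                    alpha = alpha, seed = 3, init_fit = f0)
  sel_zero <- sort(setdiff(pb$penalized, sc$positives))
  expect_true(any(vapply(oracle_patterns, identical, logical(1), sel_zero)))
})
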