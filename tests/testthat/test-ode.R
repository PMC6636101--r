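test_that("decay model matches the closed-form solution", {
  m <- decay_model()
  tr <- simulate_model(m, c(k = 0), times = c(0, 0.5, 1))
  expect_true(tr$ok)
  expect_equal(tr$states[, "x"], exp(-c(0, 0.5, 1)), tolerance = 1e-7)
  # initial condition is reproduced exactly at t = 0
  expect_equal(unname(tr$states[1, "x"]), 1)
})

test_that("linear cascade agrees with the matrix-exponential oracle", {
  m <- cascade_model()
  k <- c(k1 = 1.3, k2 = 0.4)
  A <- matrix(c(-k[1], k[1], 0, -k[2]), 2, 2)
  times <- c(0.3, 0.9, 1.7, 2.5, 4)
  tr <- simulate_model(m, log10(k), times = times)
  for (j in seq_along(times)) {
    oracle <- as.numeric(Matrix::expm(A * times[j]) %*% c(1, 0))
    expect_equal(unname(tr$states[j, ]), oracle, tolerance = 1e-6)
  }
})

test_that("sensitivities follow the chain rule on the decay model", {
  m <- decay_model()
  tr <- simulate_model(m, c(k = 0), times = c(0, 1), sens = TRUE)
  # dx/d(ln k) = -k t e^{-kt} = -e^{-1} at k = 1, t = 1; stored
  # sensitivities are with respect to log10 k
  expect_equal(tr$sens[2, "x", "k"] / log(10), -exp(-1), tolerance = 1e-4)
})

test_that("sensitivity of an unused parameter is identically zero", {
  m <- ode_model(state_names = "x", param_names = c("k", "unused"),
                 rhs = function(t, x, p) -p[["k"]] * x, x0 = 1)
  tr <- simulate_model(m, c(k = 0, unused = 0.3), times = c(0, 1, 2),
                       sens = TRUE)
  expect_equal(max(abs(tr$sens[, , "unused"])), 0)
})

test_that("cascade sensitivities agree with a central finite-difference oracle", {
  m <- cascade_model()
  lp <- log10(c(k1 = 1.3, k2 = 0.4))
  times <- c(0.5, 1.5, 3)
  tr <- simulate_model(m, lp, times = times, sens = TRUE)
  h <- 1e-4
  for (pn in c("k1", "k2")) {
    hi <- lp; hi[pn] <- hi[pn] + h
    lo <- lp; lo[pn] <- lo[pn] - h
    fd <- (simulate_model(m, hi, times)$states -
             simulate_model(m, lo, times)$states) / (2 * h)
    expect_equal(unname(tr$sens[, , pn]), unname(fd), tolerance = 1e-3)
  }
})

test_that("simulation is deterministic", {
  m <- build_network_model(3)
  ref <- attr(m, "reference_log10")
  t1 <- simulate_model(m, ref, times = seq(0, 10, 1))
  t2 <- simulate_model(m, ref, times = seq(0, 10, 1))
  expect_identical(t1$states, t2$states)
})

test_that("perturbations rescale the intended rates", {
  m <- build_network_model(6)
  ref <- attr(m, "reference_log10")
  x <- c(runif(6, 0.2, 2), runif(6, 0.2, 2))
  base <- foldreg:::hillnet_rhs(m, ref, x)

  # none leaves the model untouched
  m0 <- apply_perturbation(m, perturbation("none"))
  expect_identical(foldreg:::hillnet_rhs(m0, ref, x), base)

  # five-fold mRNA degradation: decay term of that gene's mRNA only
  g <- 3L
  m5 <- apply_perturbation(m, perturbation("degradation_x5", gene = "g3"))
  d5 <- foldreg:::hillnet_rhs(m5, ref, x)
  deg <- 10^ref[["deg"]]
  expect_equal(d5[g] - base[g], -(5 - 1) * deg * x[g], tolerance = 1e-12)
  expect_equal(d5[-g], base[-g])

  # doubled synthesis: transcription term doubles
  m2 <- apply_perturbation(m, perturbation("synthesis_x2", gene = "g3"))
  d2 <- foldreg:::hillnet_rhs(m2, ref, x)
  trans <- base[g] + deg * x[g]           # transcription part of dm_3
  expect_equal(d2[g] - base[g], trans, tolerance = 1e-10)

  # knockout: the gene is not produced at all
  mk <- apply_perturbation(m, perturbation("knockout", gene = "g3"))
  dk <- foldreg:::hillnet_rhs(mk, ref, x)
  expect_equal(dk[g], -deg * x[g], tolerance = 1e-12)      # mRNA decay only
  expect_equal(dk[6 + g], -deg * x[6 + g], tolerance = 1e-12)

  expect_error(apply_perturbation(m, perturbation("knockout", gene = "g9")),
               "unknown gene")
})

test_that("perturbation application commutes with cell-type parameter mapping", {
  m <- build_network_model(3)
  ref <- attr(m, "reference_log10")
  r <- stats::setNames(rep(0, length(ref)), names(ref))
  r[["deg"]] <- 0.3
  lp1 <- map_celltype_params(ref, r, 1L)
  pert <- perturbation("degradation_x5", gene = "g2")
  times <- seq(0, 8, length.out = 17)
  a <- simulate_model(apply_perturbation(m, pert), lp1, times)
  b <- simulate_model(m, lp1, times, condition = condition("c", perturbation = pert))
  expect_equal(a$states, b$states)
})

test_that("compiled network rates match a hand-written oracle", {
  for (ng in c(3, 6)) {
    m <- build_network_model(ng)
    ref <- attr(m, "reference_log10")
    set.seed(42 + ng)
    for (i in 1:10) {
      x <- runif(2 * ng, 0, 3)
      expect_equal(foldreg:::hillnet_rhs(m, ref, x),
                   hillnet_rhs_oracle(m, ref, x), tolerance = 1e-12)
    }
  }
})

test_that("integration failure is reported, not raised", {
  # explosive growth: dx/dt = k x^2 diverges in finite time
  m <- ode_model(state_names = "x", param_names = "k",
                 rhs = function(t, x, p) p[["k"]] * x^2, x0 = 1,
                 control = list(max_steps = 1000L))
  tr <- simulate_model(m, c(k = 2), times = c(0, 5, 10))
  expect_false(tr$ok)
})
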