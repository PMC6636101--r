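test_that("the benchmark network has the 29-parameter census", {
  m <- build_network_model(6)
  pn <- m$param_names
  expect_length(pn, 29)
  expect_length(grep("^pro_", pn), 6)     # transcription strengths
  expect_length(grep("^rbs_", pn), 6)     # ribosomal strengths
  expect_true("deg" %in% pn)              # one shared degradation rate
  expect_length(grep("^km_", pn), 8)
  expect_length(grep("^hill_", pn), 8)
  expect_length(m$state_names, 12)        # mRNA + protein per gene
  # a 6-gene topology without exactly 8 edges breaks the census
  topo <- hill_network_topology()[1:7, ]
  expect_error(hill_network_model(topo), "8")
})

test_that("all synthesis off drives every state to zero", {
  m <- build_network_model(3)
  ref <- attr(m, "reference_log10")
  for (g in m$genes) m <- apply_perturbation(m, perturbation("knockout", gene = g))
  tr <- simulate_model(m, ref, times = c(0, 20))
  expect_true(all(abs(tr$states[2, ]) < 1e-6))
})

test_that("the perturbation catalogue has 18 set-ups", {
  setups <- available_setups(build_network_model(6))
  expect_equal(nrow(setups), 18)
  expect_equal(as.integer(table(setups$kind)), c(6L, 6L, 6L))
  expect_equal(anyDuplicated(setups$id), 0L)
})

test_that("ground truth sampling respects the fold-change sets", {
  m <- build_network_model(6)
  ref <- attr(m, "reference_log10")
  truth <- sample_ground_truth(m, seed = 1)
  expect_equal(nrow(truth$table), 10)     # round(29 / 3)
  expect_equal(sum(truth$r != 0), 10)
  # identical assignment on rerun
  expect_identical(truth, sample_ground_truth(m, seed = 1))

  nonhill_set <- c(1 / 10, 1 / 5, 1 / 2, 2, 5, 10)
  hill_set <- c(1 / 4, 1 / 2, 2, 4)
  seen <- numeric()
  for (s in 1:200) {
    tt <- sample_ground_truth(m, seed = s)
    hill <- startsWith(tt$table$parameter, "hill_")
    expect_true(all(tt$table$fold[!hill] %in% nonhill_set))
    expect_true(all(tt$table$fold[hill] %in% hill_set))
    # both cell types keep Hill exponents inside [1, 4]
    prods <- 10^ref[tt$table$parameter[hill]] * tt$table$fold[hill]
    expect_true(all(prods >= 1 - 1e-9 & prods <= 4 + 1e-9))
    seen <- c(seen, tt$table$fold[!hill])
  }
  # each non-Hill fold value appears with roughly uniform frequency
  counts <- table(factor(seen, levels = nonhill_set))
  n <- length(seen)
  p <- 1 / 6
  expect_true(all(abs(counts - n * p) < 3 * sqrt(n * p * (1 - p)) + 3))
})

test_that("designs follow the stated observation modes", {
  m <- build_network_model(6)
  modes <- character(40)
  for (s in 1:40) {
    d <- sample_design(m, seed = s)
    modes[s] <- d$mode
    if (d$mode == "mrna") {
      expect_length(d$observables, 6)
      expect_length(d$times, 21)
      expect_equal(length(d$observables) * length(d$times), 126)
    } else {
      expect_length(d$observables, 2)
      expect_length(d$times, 41)
      expect_equal(length(d$observables) * length(d$times), 82)
    }
    expect_true("base" %in% names(d$conditions))
    expect_lte(length(d$conditions), 19)
  }
  # both modes occur, mRNA in roughly a third of the draws
  expect_gt(mean(modes == "mrna"), 0.1)
  expect_lt(mean(modes == "mrna"), 0.6)
})

test_that("noise-free data reproduce the simulation exactly", {
  m <- build_network_model(3)
  truth <- sample_ground_truth(m, seed = 4)
  design <- sample_design(m, seed = 4)
  d <- simulate_dataset(m, truth$r, design, seed = 4, noise_free = TRUE)
  row <- d[17, ]
  lp <- attr(m, "reference_log10")
  if (row$cellType == 1) lp <- map_celltype_params(lp, truth$r, 1L)
  tr <- simulate_model(m, lp, times = row$time,
                       condition = design$conditions[[row$conditionId]])
  expect_equal(row$measurement, unname(tr$states[1, row$observableId]),
               tolerance = 1e-8)
})

test_that("identical cell types give identical measurements", {
  m <- build_network_model(3)
  r0 <- stats::setNames(rep(0, length(m$param_names)), m$param_names)
  design <- sample_design(m, seed = 9)
  d <- simulate_dataset(m, r0, design, seed = 9, noise_free = TRUE)
  wide <- tidyr::pivot_wider(d, names_from = "cellType",
                             values_from = "measurement",
                             id_cols = c("observableId", "conditionId",
                                         "time"))
  expect_equal(wide$`0`, wide$`1`, tolerance = 1e-12)
})

test_that("measurement noise is Gaussian with the recorded sd", {
  m <- build_network_model(3)
  truth <- sample_ground_truth(m, seed = 12)
  design <- sample_design(m, seed = 12)
  clean <- simulate_dataset(m, truth$r, design, seed = 12, noise_free = TRUE)
  noisy <- simulate_dataset(m, truth$r, design, seed = 12)
  z <- (noisy$measurement - clean$measurement) / noisy$sd
  expect_gt(length(z), 300)
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
})

test_that("classification metrics follow their definitions", {
  universe <- paste0("p", 1:29)
  truth <- universe[1:10]
  # perfect prediction
  m <- classify(truth, truth, universe)
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy), c(1, 1, 1))
  # 19 of 22 negatives correct: specificity 86.4%
  m2 <- classify(c(truth[1:7], universe[11:13]), truth[1:7],
                 universe[1:29][c(1:7, 8:29)])
  expect_equal(m2$specificity, 19 / 22, tolerance = 1e-12)
  # all-negative predictor on 10 positives / 19 negatives
  m3 <- classify(character(), truth, universe)
  expect_equal(m3$sensitivity, 0)
  expect_equal(m3$specificity, 1)
  expect_equal(m3$accuracy, 19 / 29)
})

test_that("paired study deltas reproduce hand-computed t-tests", {
  metrics <- dplyr::bind_rows(
    tibble::tibble(run = 1:3, method = "l1",
                   sensitivity = c(0.5, 0.6, 0.7),
                   specificity = c(0.6, 0.5, 0.7),
                   accuracy = c(0.55, 0.55, 0.7)),
    tibble::tibble(run = 1:3, method = "lq",
                   sensitivity = c(0.5, 0.6, 0.7),
                   specificity = c(0.8, 0.8, 0.8),
                   accuracy = c(0.65, 0.7, 0.75)))
  d <- foldreg:::study_deltas(metrics, c("l1", "lq"))
  spec_row <- d[d$comparison == "l1 -> lq" & d$measure == "specificity", ]
  delta <- c(0.2, 0.3, 0.1)
  expect_equal(spec_row$mean_delta, mean(delta))
  expect_equal(spec_row$p_value, stats::t.test(delta)$p.value)
  # a method against itself is never significant
  l1 <- metrics[metrics$method == "l1", ]
  copy <- l1
  copy$method <- "lq"
  same <- foldreg:::study_deltas(dplyr::bind_rows(l1, copy), c("l1", "lq"))
  expect_true(all(same$mean_delta == 0))
  expect_false(any(same$significant, na.rm = TRUE))
  # Bonferroni divides the 5% level by the number of tests: one pair
  # of methods gives 3 tests here, the full default comparison set (4
  # pairs x 3 measures) gives the 5%/12 = 0.42% level
  expect_equal(unique(d$level), 0.05 / 3)
  four <- dplyr::bind_rows(lapply(c("l1", "lq", "al", "en"), function(mm) {
    x <- metrics[metrics$method == "l1", ]
    x$method <- mm
    x
  }))
  d4 <- foldreg:::study_deltas(four, c("l1", "lq", "al", "en"))
  expect_equal(unique(d4$level), 0.05 / 12)
})

test_that("ROC endpoints behave like a shrinkage path", {
  universe <- paste0("p", 1:6)
  truth <- universe[1:2]
  refits <- list(
    structure(list(r = stats::setNames(rep(0.5, 6), universe)),
              class = "fr_fit"),
    structure(list(r = stats::setNames(c(0.5, 0.5, 0, 0, 0, 0), universe)),
              class = "fr_fit"),
    structure(list(r = stats::setNames(rep(0, 6), universe)),
              class = "fr_fit"))
  path <- structure(list(
    path = tibble::tibble(lambda = c(0.1, 1, 10), ok = TRUE,
                          zero = lapply(refits, function(f) zero_set(f$r)),
                          n_zero = c(0L, 4L, 6L),
                          refit = refits),
    problem = list(penalized = universe)), class = "fr_regpath")
  roc <- roc_points(path, truth)
  expect_equal(roc$fpr, c(1, 0, 0))
  expect_equal(roc$tpr, c(1, 1, 0))
})

test_that("benchmark runs are reproducible from the master seed", {
  a <- make_benchmark_run(123, n_genes = 3)
  b <- make_benchmark_run(123, n_genes = 3)
  expect_identical(a$truth, b$truth)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$design$setups, b$design$setups)
  c2 <- make_benchmark_run(124, n_genes = 3)
  expect_false(identical(a$measurements, c2$measurements))
})

test_that("deformation zero reproduces the l1 scan", {
  pb <- const_problem(b = c(p1 = 0.7, p2 = 0.02), sigma = 0.1)
  f0 <- fit_ml(pb, n_starts = 1, seed = 1)
  grid <- 10^seq(-1, 3, length.out = 7)
  sc_l1 <- scan_lambda(pb, penalty_spec("l1"), grid, seed = 1, init_fit = f0)
  ds <- deformation_scan(pb, "elastic_net", d_grid = c(0, 0.5),
                         lambda_grid = grid, seed = 1, init_fit = f0)
  expect_equal(ds$results$lambda_star[1], sc_l1$lambda_star)
  expect_identical(sort(ds$results$positives[[1]]), sort(sc_l1$positives))
  # high elasticity shrinks no harder than the l1 limit
  expect_lte(ds$results$n_positive[1], ds$results$n_positive[2] + 1)
})
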