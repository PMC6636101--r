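#' Build the benchmark gene-network model
#'
#' Convenience wrapper around [hill_network_model()] for the built-in
#' 6-gene (29 kinetic parameters) or 3-gene reduction.
#'
#' @param n_genes 6 or 3.
#' @param control integrator settings passed to [hill_network_model()].
#' @return an `fr_model`.
#' @export
build_network_model <- function(n_genes = 6, control = list()) {
  hill_network_model(hill_network_topology(n_genes), control = control)
}

#' Catalogue of available perturbation set-ups
#'
#' For each gene: a knockout (the gene is not produced at all), a
#' five-fold increased mRNA degradation rate, and a doubled mRNA
#' synthesis rate — 18 set-ups for the 6-gene network.
#'
#' @param model a gene-network `fr_model`.
#' @return tibble with columns `id`, `kind`, `gene`.
#' @export
available_setups <- function(model) {
  stopifnot(model$backend == "hillnet")
  kinds <- c("knockout", "degradation_x5", "synthesis_x2")
  short <- c(knockout = "ko", degradation_x5 = "deg5", synthesis_x2 = "syn2")
  tidyr::expand_grid(kind = kinds, gene = model$genes) |>
    dplyr::mutate(id = paste(short[.data$kind], .data$gene, sep = "_")) |>
    dplyr::select("id", "kind", "gene")
}

#' Sample a ground-truth fold-change assignment
#'
#' Chooses which kinetic parameters are cell-type specific (10 of the 29
#' for the 6-gene network, i.e. one third rounded) and draws their
#' fold-changes: non-Hill parameters uniformly from
#' \{1/10, 1/5, 1/2, 2, 5, 10\}, Hill exponents from \{1/4, 1/2, 2, 4\}
#' restricted to the candidates that keep both cell types' exponents
#' inside \[1, 4\]. Deterministic given the seed.
#'
#' @param model a gene-network `fr_model` (with reference values
#'   attached).
#' @param seed integer seed.
#' @param n_specific number of cell-type specific parameters; default
#'   `round(n_parameters / 3)`.
#' @return list with `table` (tibble: `parameter`, `fold`, `r`) and `r`
#'   (named log10 fold-change vector over all parameters, zero for the
#'   cell-type independent ones).
#' @export
sample_ground_truth <- function(model, seed, n_specific = NULL) {
  params <- model$param_names
  ref <- attr(model, "reference_log10")
  n_specific <- n_specific %||% round(length(params) / 3)
  nonhill_folds <- c(1 / 10, 1 / 5, 1 / 2, 2, 5, 10)
  hill_folds <- c(1 / 4, 1 / 2, 2, 4)
  with_seed(seed, {
    chosen <- sample(params, n_specific)
    fold <- vapply(chosen, function(pn) {
      if (startsWith(pn, "hill_")) {
        n_ref <- 10^ref[[pn]]
        adm <- hill_folds[n_ref * hill_folds >= 1 & n_ref * hill_folds <= 4]
        if (length(adm) == 1) adm else sample(adm, 1)
      } else {
        sample(nonhill_folds, 1)
      }
    }, numeric(1))
    r <- stats::setNames(rep(0, length(params)), params)
    r[chosen] <- log10(fold)
    list(table = tibble::tibble(parameter = chosen, fold = unname(fold),
                                r = log10(unname(fold))),
         r = r)
  })
}

# Time horizon after which every state of the unperturbed reference model
# has settled to within 10% of its late-time value. The horizon is capped
# at `t_cap` (with the shared degradation rate of 1 the relaxation time
# is ~1, so 20 time units cover the transient; networks with sustained
# small-amplitude oscillations would otherwise never satisfy the
# settling criterion).
settle_time <- function(model, horizon = 40, frac = 0.9, t_cap = 20) {
  ref <- attr(model, "reference_log10")
  times <- seq(0, horizon, length.out = 241)
  traj <- simulate_model(model, ref, times)
  if (!traj$ok) stop("reference model failed to integrate")
  xe <- traj$states[nrow(traj$states), ]
  tol <- pmax((1 - frac) * abs(xe), 1e-3)
  settled <- apply(abs(sweep(traj$states, 2, xe)) <=
                     matrix(tol, nrow(traj$states), ncol(traj$states),
                            byrow = TRUE), 1, all)
  # last time before which some state was still away from steady state
  k <- max(which(!settled), 0) + 1
  min(ceiling(times[min(k, length(times))]), t_cap)
}

#' Sample an experimental design
#'
#' The unperturbed base condition is always measured; each of the 18
#' perturbation set-ups is included independently with probability
#' `p_setup`. With probability 1/3 all mRNAs are observed on a 21-point
#' grid; otherwise two randomly chosen proteins are observed on a
#' 41-point grid. Both cell types are measured under every selected
#' condition. Time grids are uniform over \[0, `t_max`\], where the
#' default horizon lets the unperturbed reference reach at least 90% of
#' its steady state.
#'
#' @param model a gene-network `fr_model`.
#' @param seed integer seed.
#' @param p_setup inclusion probability per perturbation set-up.
#' @param t_max observation horizon; default [settle_time()].
#' @return list with `setups` (selected perturbations), `conditions`
#'   (named list of [condition()]), `observables`, `times`, `mode`,
#'   `t_max`.
#' @export
sample_design <- function(model, seed, p_setup = 0.5, t_max = NULL) {
  cat18 <- available_setups(model)
  t_max <- t_max %||% settle_time(model)
  with_seed(seed, {
    keep <- stats::runif(nrow(cat18)) < p_setup
    setups <- cat18[keep, ]
    mrna_mode <- stats::runif(1) < 1 / 3
    if (mrna_mode) {
      observables <- paste0("mrna_", model$genes)
      times <- seq(0, t_max, length.out = 21)
    } else {
      observables <- paste0("protein_", sample(model$genes, 2))
      times <- seq(0, t_max, length.out = 41)
    }
    conds <- c(list(condition("base")),
               purrr::pmap(setups, function(id, kind, gene) {
                 condition(id, perturbation = perturbation(kind, gene = gene))
               }))
    names(conds) <- vapply(conds, `[[`, "", "id")
    list(setups = setups, conditions = conds, observables = observables,
         times = times, mode = if (mrna_mode) "mrna" else "protein",
         t_max = t_max)
  })
}

#' Simulate a noisy two-cell-type data set
#'
#' Simulates both cell types under every condition of the design and
#' adds Gaussian noise with known standard deviations
#' \eqn{\sigma_{ij} = \max(rel \cdot |y_{ij}|,\ floor \cdot range_i)}
#' (10% relative with a 1%-of-signal-range floor by default); the
#' standard deviations are recorded in the output and treated as known
#' during estimation.
#'
#' @param model a gene-network `fr_model`.
#' @param truth_r named log10 fold-change vector (cell type 1 relative
#'   to the reference).
#' @param design output of [sample_design()].
#' @param seed seed for the measurement noise.
#' @param noise list with `rel` and `floor_frac`.
#' @param noise_free skip the noise (measurements equal the model
#'   output; `sd` still recorded).
#' @return measurement tibble (`observableId`, `conditionId`,
#'   `cellType`, `time`, `measurement`, `sd`).
#' @export
simulate_dataset <- function(model, truth_r, design, seed,
                             noise = list(rel = 0.1, floor_frac = 0.01),
                             noise_free = FALSE) {
  ref <- attr(model, "reference_log10")
  sidx <- match(design$observables, model$state_names)
  stopifnot(!anyNA(sidx))
  rows <- list()
  for (ct in 0:1) {
    lp <- if (ct == 0) ref else map_celltype_params(ref, truth_r, 1L)
    for (cond in design$conditions) {
      traj <- simulate_model(model, lp, design$times, condition = cond)
      if (!traj$ok)
        stop("benchmark simulation failed for condition ", cond$id,
             ", cell type ", ct)
      for (j in seq_along(design$observables)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          observableId = design$observables[j],
          conditionId = cond$id,
          cellType = ct,
          time = design$times,
          signal = traj$states[, sidx[j]])
      }
    }
  }
  d <- dplyr::bind_rows(rows)
  rng <- d |> dplyr::group_by(.data$observableId) |>
    dplyr::summarise(range = max(.data$signal) - min(.data$signal))
  d <- dplyr::left_join(d, rng, by = "observableId")
  d$sd <- pmax(noise$rel * abs(d$signal), noise$floor_frac * d$range, 1e-6)
  d$measurement <- if (noise_free) d$signal else
    with_seed(seed, d$signal + stats::rnorm(nrow(d), sd = d$sd))
  dplyr::select(d, dplyr::all_of(measurement_cols))
}

#' Generate one complete benchmark run
#'
#' Ground truth, experimental design and noisy measurements for one
#' synthetic two-cell-type study, all reproducible from the single
#' master seed.
#'
#' @param seed master seed of the run.
#' @param n_genes network size (6 or 3).
#' @param p_setup perturbation inclusion probability.
#' @param noise noise configuration, see [simulate_dataset()].
#' @param noise_free simulate without noise.
#' @param n_specific number of cell-type specific parameters.
#' @param model_control integrator settings for the model used in the
#'   run (data are always generated at rtol 1e-8).
#' @return an `fr_benchmark_run`: list with `model`, `truth`, `design`,
#'   `measurements`, `seed`.
#' @export
make_benchmark_run <- function(seed, n_genes = 6, p_setup = 0.5,
                               noise = list(rel = 0.1, floor_frac = 0.01),
                               noise_free = FALSE, n_specific = NULL,
                               model_control = list()) {
  gen_model <- build_network_model(n_genes)
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  truth <- sample_ground_truth(gen_model, sub[1], n_specific)
  design <- sample_design(gen_model, sub[2], p_setup)
  measurements <- simulate_dataset(gen_model, truth$r, design, sub[3],
                                   noise, noise_free)
  model_control <- utils::modifyList(
    list(rtol = 1e-6, atol = 1e-8, sens_err_states = TRUE,
         max_steps = 20000L), model_control)
  fit_model <- build_network_model(n_genes, control = model_control)
  structure(list(model = fit_model, truth = truth, design = design,
                 measurements = measurements, seed = seed),
            class = "fr_benchmark_run")
}

#' Estimation problem for a benchmark run
#'
#' @param run an `fr_benchmark_run`.
#' @param control optimizer control for the fits (defaults tuned for
#'   path scans: 3 multi-starts).
#' @return an `fr_problem` with fold-changes on every kinetic parameter.
#' @export
benchmark_problem <- function(run, control = list()) {
  ctrl <- utils::modifyList(list(n_starts = 3L, maxit = 100L,
                                 ml_maxit = 120L, factr = 1e7,
                                 step1_maxit = 15L,
                                 step1_active_maxit = 25L,
                                 step1_factr = 1e9,
                                 scout_maxit = 50L, refit_scout = 30L,
                                 confirm_maxit = 40L, confirm_margin = 25,
                                 prox_iter = 10L,
                                 step1_rtol = 1e-4, step1_atol = 1e-6),
                            control)
  fc_problem(run$model, run$measurements, run$design$conditions,
             penalized = run$model$param_names, control = ctrl)
}

#' Classification metrics against the ground truth
#'
#' A fold-change estimated nonzero is a positive prediction; comparison
#' with the true assignment yields the confusion counts, sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP) and accuracy (TP+TN)/total.
#'
#' @param positives parameters predicted cell-type specific.
#' @param truth_positives parameters truly cell-type specific.
#' @param universe all penalized parameters.
#' @return one-row tibble of counts and rates.
#' @export
classify <- function(positives, truth_positives, universe) {
  stopifnot(all(positives %in% universe), all(truth_positives %in% universe))
  tp <- length(intersect(positives, truth_positives))
  fp <- length(setdiff(positives, truth_positives))
  fn <- length(setdiff(truth_positives, positives))
  tn <- length(universe) - tp - fp - fn
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(universe))
}

#' ROC points along a regularization path
#'
#' One (FPR, TPR) point per penalty strength, based on each grid point's
#' step-2 zero pattern.
#'
#' @param path an `fr_regpath`.
#' @param truth_positives truly cell-type specific parameters.
#' @return tibble with `lambda`, `fpr`, `tpr`, `n_zero`.
#' @export
roc_points <- function(path, truth_positives) {
  universe <- path$problem$penalized
  rows <- dplyr::filter(path$path, .data$ok)
  purrr::map_dfr(seq_len(nrow(rows)), function(k) {
    Z <- rows$zero[[k]]
    m <- classify(setdiff(universe, Z), truth_positives, universe)
    tibble::tibble(lambda = rows$lambda[k], fpr = 1 - m$specificity,
                   tpr = m$sensitivity, n_zero = rows$n_zero[k])
  })
}

default_methods <- function() {
  list(l1 = penalty_spec("l1"),
       lq = penalty_spec("lq", deformation = 0.2),
       al = penalty_spec("adaptive_lasso", deformation = 0.2),
       en = penalty_spec("elastic_net", deformation = 0.08))
}

#' Run a simulation study over penalty families
#'
#' Repeats the full pipeline (sample a two-cell-type benchmark model,
#' simulate data, scan each penalty family, select the parsimonious
#' model, classify) over independently randomized runs. All penalty
#' families see the same data sets and share the unpenalized fit per
#' run, so method differences are paired. Per-method means and paired
#' point-wise changes (with t-tests at a Bonferroni-corrected level,
#' 5%/12 = 0.42% for the default 4 pairs x 3 metrics) are summarized.
#'
#' @param n_runs number of benchmark runs (the full-scale study uses
#'   150; reduced profiles use 25).
#' @param methods named list of [penalty_spec()] objects; the default
#'   compares l1, lq (q = 0.8), Adaptive Lasso (gamma = 0.2) and Elastic
#'   Net (alpha = 0.08).
#' @param seed master seed; run `k` uses `seed + k`.
#' @param lambda_grid penalty-strength grid.
#' @param alpha level of the likelihood-ratio selection.
#' @param n_genes,p_setup,noise,model_control benchmark configuration,
#'   see [make_benchmark_run()].
#' @param fit_control optimizer control, see [benchmark_problem()].
#' @param progress print one line per run.
#' @return an `fr_study`: list with `metrics` (per run and method),
#'   `summary`, `deltas` (paired comparisons), `failed`, `config`.
#' @export
run_study <- function(n_runs = 150, methods = default_methods(), seed = 1L,
                      lambda_grid = default_lambda_grid(),
                      alpha = 0.95, n_genes = 6, p_setup = 0.5,
                      noise = list(rel = 0.1, floor_frac = 0.01),
                      model_control = list(), fit_control = list(),
                      progress = FALSE) {
  metrics <- list()
  failed <- integer()
  for (k in seq_len(n_runs)) {
    run_seed <- seed + k
    res <- try({
      run <- make_benchmark_run(run_seed, n_genes = n_genes,
                                p_setup = p_setup, noise = noise,
                                model_control = model_control)
      problem <- benchmark_problem(run, control = fit_control)
      fit0 <- fit_ml(problem, seed = run_seed)
      truth_pos <- run$truth$table$parameter
      cache <- new.env(parent = emptyenv())
      purrr::imap_dfr(methods, function(spec, mname) {
        t0 <- proc.time()[["elapsed"]]
        sc <- scan_lambda(problem, spec, lambda_grid, alpha = alpha,
                          seed = run_seed, init_fit = fit0,
                          refit_cache = cache)
        m <- classify(sc$positives, truth_pos, problem$penalized)
        dplyr::mutate(m, run = k, seed = run_seed, method = mname,
                      lambda_star = sc$lambda_star,
                      n_zero = length(problem$penalized) - length(sc$positives),
                      chi2_0 = sc$chi2_0,
                      elapsed = proc.time()[["elapsed"]] - t0,
                      .before = 1)
      })
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failed <- c(failed, k)
      warning("benchmark run ", k, " failed and is excluded: ",
              attr(res, "condition")$message)
      next
    }
    metrics[[length(metrics) + 1]] <- res
    if (progress)
      message(sprintf("run %d/%d done (%s)", k, n_runs,
                      paste(sprintf("%s acc %.2f", res$method, res$accuracy),
                            collapse = ", ")))
  }
  metrics <- dplyr::bind_rows(metrics)
  structure(list(metrics = metrics,
                 summary = study_summary(metrics),
                 deltas = study_deltas(metrics, names(methods)),
                 failed = failed,
                 config = list(n_runs = n_runs, seed = seed, alpha = alpha,
                               n_genes = n_genes, p_setup = p_setup,
                               noise = noise,
                               methods = lapply(methods, unclass))),
            class = "fr_study")
}

study_summary <- function(metrics) {
  metrics |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(c("sensitivity", "specificity", "accuracy"),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~stats::sd(.x, na.rm = TRUE))),
                     n = dplyr::n())
}

# Paired point-wise changes between methods: extended families vs l1,
# and adaptive lasso vs lq, on sensitivity/specificity/accuracy.
study_deltas <- function(metrics, method_names,
                         pairs = NULL, total_level = 0.05) {
  if (is.null(pairs)) {
    pairs <- list(c("l1", "al"), c("l1", "lq"), c("al", "lq"), c("l1", "en"))
    pairs <- Filter(function(p) all(p %in% method_names), pairs)
  }
  measures <- c("sensitivity", "specificity", "accuracy")
  n_tests <- length(pairs) * length(measures)
  level <- total_level / max(n_tests, 1)
  out <- list()
  for (pr in pairs) {
    a <- metrics[metrics$method == pr[1], c("run", measures)]
    b <- metrics[metrics$method == pr[2], c("run", measures)]
    j <- dplyr::inner_join(a, b, by = "run", suffix = c("_a", "_b"))
    for (ms in measures) {
      d <- j[[paste0(ms, "_b")]] - j[[paste0(ms, "_a")]]
      d <- d[is.finite(d)]
      tt <- try(stats::t.test(d), silent = TRUE)
      p <- if (inherits(tt, "try-error")) NA_real_ else tt$p.value
      out[[length(out) + 1]] <- tibble::tibble(
        comparison = paste(pr[1], "->", pr[2]), measure = ms,
        mean_delta = mean(d), sd_delta = stats::sd(d), n = length(d),
        p_value = p, level = level,
        significant = !is.na(p) & p < level)
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.fr_study <- function(x, ...) {
  cat("<fr_study>", x$config$n_runs, "runs,",
      length(unique(x$metrics$method)), "methods,",
      length(x$failed), "failed\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.fr_study <- function(x, ...) x$metrics

#' @export
glance.fr_study <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(x$deltas, "comparison", "measure", "mean_delta"),
    names_from = "measure", values_from = "mean_delta",
    names_prefix = "delta_")
}

#' Plot paired study differences
#'
#' Boxplots of the run-wise changes in sensitivity, specificity and
#' accuracy for each method comparison.
#'
#' @param object an `fr_study`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fr_study <- function(object, ...) {
  measures <- c("sensitivity", "specificity", "accuracy")
  wide <- tidyr::pivot_wider(
    dplyr::select(object$metrics, "run", "method",
                  dplyr::all_of(measures)),
    names_from = "method", values_from = dplyr::all_of(measures))
  long <- purrr::map_dfr(unique(object$deltas$comparison), function(cmp) {
    pr <- strsplit(cmp, " -> ")[[1]]
    purrr::map_dfr(measures, function(ms) {
      tibble::tibble(comparison = cmp, measure = ms,
                     delta = wide[[paste(ms, pr[2], sep = "_")]] -
                       wide[[paste(ms, pr[1], sep = "_")]])
    })
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$comparison, .data$delta)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "point-wise change")
}

#' Scan the deformation parameter of a penalty family
#'
#' Runs the full two-step regularization scan for each deformation value
#' and tabulates the parsimonious model per deformation. At deformation
#' 0 every family reduces to the l1 penalty. The unpenalized fit is
#' shared across deformations.
#'
#' @param problem an `fr_problem`.
#' @param family `"lq"`, `"adaptive_lasso"` or `"elastic_net"`.
#' @param d_grid deformation values.
#' @param lambda_grid penalty-strength grid.
#' @param alpha selection level.
#' @param seed seed for the shared unpenalized fit.
#' @param init_fit optional precomputed unpenalized fit.
#' @return an `fr_deformation_scan`: tibble with one row per deformation
#'   (`deformation`, `lambda_star`, `n_positive`, `positives`,
#'   `estimates`, `elapsed`), plus the family and the shared fit.
#' @export
deformation_scan <- function(problem, family, d_grid,
                             lambda_grid = default_lambda_grid(),
                             alpha = 0.95, seed = 1L, init_fit = NULL) {
  fit0 <- init_fit %||% fit_ml(problem, seed = seed)
  rows <- purrr::map_dfr(d_grid, function(d) {
    t0 <- proc.time()[["elapsed"]]
    spec <- penalty_spec(family, deformation = d)
    sc <- try(scan_lambda(problem, spec, lambda_grid, alpha = alpha,
                          seed = seed, init_fit = fit0), silent = TRUE)
    if (inherits(sc, "try-error")) {
      return(tibble::tibble(deformation = d, ok = FALSE,
                            lambda_star = NA_real_, n_positive = NA_integer_,
                            positives = list(character()),
                            estimates = list(NULL),
                            elapsed = proc.time()[["elapsed"]] - t0))
    }
    est <- sc$final_fit$r[sc$positives]
    tibble::tibble(deformation = d, ok = TRUE, lambda_star = sc$lambda_star,
                   n_positive = length(sc$positives),
                   positives = list(sc$positives), estimates = list(est),
                   elapsed = proc.time()[["elapsed"]] - t0)
  })
  structure(list(results = rows, family = family, fit0 = fit0,
                 alpha = alpha), class = "fr_deformation_scan")
}

#' @export
print.fr_deformation_scan <- function(x, ...) {
  cat("<fr_deformation_scan>", x$family, "over",
      nrow(x$results), "deformations\n")
  print(dplyr::select(x$results, "deformation", "lambda_star", "n_positive",
                      "elapsed"))
  invisible(x)
}

#' @export
tidy.fr_deformation_scan <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$results)), function(k) {
    row <- x$results[k, ]
    est <- row$estimates[[1]]
    if (is.null(est) || length(est) == 0)
      return(tibble::tibble(deformation = row$deformation,
                            parameter = character(), estimate = numeric()))
    tibble::tibble(deformation = row$deformation, parameter = names(est),
                   estimate = unname(est))
  })
}
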