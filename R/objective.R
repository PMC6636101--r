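#' Map reference parameters and fold-changes to one cell type
#'
#' Cell type 0 is the reference; cell type 1 differs by log10 fold-changes
#' `r` on the penalized parameter subset: `log10 p[1]_i = log10 p[0]_i +
#' r_i`. A fold-change of exactly zero means the parameter is cell-type
#' independent.
#'
#' @param log_p0 named log10 reference parameter vector.
#' @param r named log10 fold-change vector (names are a subset of
#'   `names(log_p0)`).
#' @param cell_type 0 or 1.
#' @return named log10 parameter vector for the requested cell type.
#' @export
map_celltype_params <- function(log_p0, r, cell_type) {
  stopifnot(cell_type %in% c(0L, 1L))
  if (cell_type == 0L) return(log_p0)
  bad <- setdiff(names(r), names(log_p0))
  if (length(bad)) stop("fold-changes for unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  out <- log_p0
  out[names(r)] <- out[names(r)] + r
  out
}

measurement_cols <- c("observableId", "conditionId", "cellType", "time",
                      "measurement", "sd")

validate_measurements <- function(measurements, model, conditions) {
  miss <- setdiff(measurement_cols, names(measurements))
  if (length(miss))
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(measurements$observableId %in% model$observables$name))
  if (length(bad))
    stop("measurement row ", bad[1], ": unknown observable '",
         measurements$observableId[bad[1]], "'")
  bad <- which(!(measurements$conditionId %in% names(conditions)))
  if (length(bad))
    stop("measurement row ", bad[1], ": unknown condition '",
         measurements$conditionId[bad[1]], "'")
  bad <- which(!(measurements$cellType %in% c(0, 1)))
  if (length(bad))
    stop("measurement row ", bad[1], ": cellType must be 0 or 1")
  bad <- which(!(measurements$sd > 0))
  if (length(bad))
    stop("measurement row ", bad[1], ": sd must be positive")
  invisible(measurements)
}

#' Assemble a two-cell-type estimation problem
#'
#' Bundles a model, its experimental conditions and a measurement table
#' into the object all fitting functions operate on. The declared
#' `penalized` parameters carry log10 fold-changes between the two cell
#' types; `fixed_zero` entries are held at exactly zero during every fit.
#'
#' @param model an `fr_model`.
#' @param measurements tibble with columns `observableId`, `conditionId`,
#'   `cellType`, `time`, `measurement`, `sd` (all `sd > 0`).
#' @param conditions named list of [condition()] objects; names must
#'   match `conditionId` values.
#' @param penalized parameter names that receive fold-changes (default:
#'   all model parameters).
#' @param fixed_zero subset of `penalized` whose fold-changes are masked
#'   to exactly zero.
#' @param fold_bounds tibble (`name`, `lower`, `upper`) of log10 bounds
#'   for the fold-changes; default \[-3, 3\] (Hill-exponent fold-changes
#'   in network models are clamped to \[-log10(4), log10(4)\] so both
#'   cell types keep exponents in \[1, 4\]).
#' @param control list: `n_starts` (default 10), `maxit` (default 300),
#'   `factr` (optimizer tolerance, default 1e7).
#' @return an object of class `fr_problem`.
#' @export
fc_problem <- function(model, measurements, conditions,
                       penalized = model$param_names,
                       fixed_zero = character(),
                       fold_bounds = NULL, control = list()) {
  stopifnot(inherits(model, "fr_model"))
  measurements <- tibble::as_tibble(measurements)
  if (is.null(names(conditions)))
    names(conditions) <- vapply(conditions, `[[`, "", "id")
  validate_measurements(measurements, model, conditions)
  stopifnot(all(penalized %in% model$param_names),
            all(fixed_zero %in% penalized))
  if (is.null(fold_bounds)) {
    fold_bounds <- tibble::tibble(
      name = penalized,
      lower = ifelse(startsWith(penalized, "hill_"), -log10(4), -3),
      upper = ifelse(startsWith(penalized, "hill_"), log10(4), 3))
  }
  stopifnot(all(penalized %in% fold_bounds$name))
  ctrl <- utils::modifyList(list(n_starts = 10L, maxit = 300L, factr = 1e7),
                            control)
  groups <- build_groups(measurements, model)
  # pre-apply each condition's perturbation once
  groups <- lapply(groups, function(grp) {
    grp$pmodel <- apply_perturbation(model,
                                     conditions[[grp$conditionId]]$perturbation)
    grp
  })
  # gene-network problems with plain state observations evaluate the
  # whole objective in one compiled call
  fastplan <- NULL
  if (model$backend == "hillnet" &&
      all(model$observables$transform == "identity")) {
    fastplan <- lapply(groups, function(grp) {
      ord <- order(grp$t_idx)
      list(ct = as.integer(grp$cell_type),
           tmul = grp$pmodel$tmul, lmul = grp$pmodel$lmul,
           dmul = grp$pmodel$dmul,
           times = as.numeric(grp$times),
           t_idx = as.integer(grp$t_idx[ord]),
           s_idx = as.integer(grp$s_idx[ord]),
           y = as.numeric(grp$y[ord]), sd = as.numeric(grp$sd[ord]))
    })
  }
  structure(list(model = model, measurements = measurements,
                 conditions = conditions, penalized = penalized,
                 fixed_zero = fixed_zero, fold_bounds = fold_bounds,
                 control = ctrl, groups = groups, fastplan = fastplan),
            class = "fr_problem")
}

# Pre-index measurements by (condition, cell type) for fast objective
# evaluation; ordering of the input records does not matter.
build_groups <- function(measurements, model) {
  key <- paste(measurements$conditionId, measurements$cellType, sep = "\r")
  lapply(split(seq_len(nrow(measurements)), key), function(idx) {
    rows <- measurements[idx, ]
    times <- sort(unique(rows$time))
    obs <- model$observables[match(rows$observableId, model$observables$name), ]
    list(conditionId = rows$conditionId[1],
         cell_type = as.integer(rows$cellType[1]),
         times = times,
         t_idx = match(rows$time, times),
         state = obs$state,
         s_idx = match(obs$state, model$state_names),
         transform = obs$transform,
         y = rows$measurement,
         sd = rows$sd)
  })
}

#' @export
print.fr_problem <- function(x, ...) {
  cat("<fr_problem>", nrow(x$measurements), "measurements,",
      length(x$conditions), "conditions,",
      length(x$penalized), "penalized fold-changes\n")
  invisible(x)
}

#' Maximum-likelihood objective for the two-cell-type model
#'
#' Computes the weighted residual sum of squares
#' \deqn{\chi^2_{ML} = \sum_{i,j} ((y_{ij} - g(x_i(t_j))) / \sigma_{ij})^2}
#' over all conditions and both cell types (the additive normalization
#' constant of the log-likelihood is dropped), together with its gradient
#' with respect to the log10 reference parameters and the fold-changes.
#' Integration failures yield `Inf` with a zero gradient so optimizers
#' reject the point.
#'
#' @param problem an `fr_problem`.
#' @param log_p0 named log10 reference parameters (all model parameters).
#' @param r named log10 fold-changes over the penalized subset (missing
#'   entries count as zero).
#' @param gradient compute the gradient as well?
#' @return list with `value`, and if requested `grad_p0` and `grad_r`.
#' @export
chi2_ml <- function(problem, log_p0, r = NULL, gradient = FALSE) {
  model <- problem$model
  rfull <- stats::setNames(rep(0, length(problem$penalized)), problem$penalized)
  if (!is.null(r)) rfull[names(r)] <- r
  g_p0 <- stats::setNames(rep(0, length(model$param_names)), model$param_names)
  g_r <- stats::setNames(rep(0, length(problem$penalized)), problem$penalized)
  if (!is.null(problem$fastplan)) {
    p0n <- 10^unname(log_p0[model$param_names])
    lp1 <- map_celltype_params(log_p0, rfull, 1L)
    p1n <- 10^unname(lp1[model$param_names])
    out <- hillnet_obj_cpp(model$net, p0n, p1n, model$x0(p0n),
                           problem$fastplan, gradient,
                           model$control$rtol, model$control$atol,
                           as.integer(model$control$max_steps),
                           as.integer(model$control$order %||% 5L))
    if (!isTRUE(out$ok))
      return(list(value = Inf, grad_p0 = g_p0, grad_r = g_r, ok = FALSE))
    res <- list(value = out$value, ok = TRUE)
    if (gradient) {
      res$grad_p0 <- g_p0 + out$g0 + out$g1
      res$grad_r <- g_r + out$g1[match(problem$penalized, model$param_names)]
    }
    return(res)
  }
  value <- 0
  for (grp in problem$groups) {
    lp <- map_celltype_params(log_p0, rfull, grp$cell_type)
    traj <- simulate_model(grp$pmodel, lp, grp$times, sens = gradient)
    if (!traj$ok)
      return(list(value = Inf, grad_p0 = g_p0, grad_r = g_r, ok = FALSE))
    xi <- traj$states[cbind(grp$t_idx, grp$s_idx)]
    gi <- xi
    is_log <- grp$transform == "log10"
    if (any(is_log)) {
      if (any(xi[is_log] <= 0))
        return(list(value = Inf, grad_p0 = g_p0, grad_r = g_r, ok = FALSE))
      gi[is_log] <- log10(xi[is_log])
    }
    res <- (grp$y - gi) / grp$sd
    value <- value + sum(res^2)
    if (gradient) {
      # dchi2/dtheta = sum -2 res/sd * dg/dtheta, theta = log10 params
      w <- -2 * res / grp$sd
      dg_fac <- ifelse(is_log, 1 / (xi * log(10)), 1)
      nt <- length(grp$times)
      ns <- length(model$state_names)
      # sens array is (time, state, parameter); flatten to rows of
      # (time, state) so one colSums yields the whole gradient block
      Sm <- matrix(traj$sens, nrow = nt * ns)
      g <- colSums((w * dg_fac) * Sm[grp$t_idx + (grp$s_idx - 1) * nt, ,
                                     drop = FALSE])
      g_p0 <- g_p0 + g
      if (grp$cell_type == 1L) {
        pen_idx <- match(problem$penalized, model$param_names)
        g_r <- g_r + g[pen_idx]
      }
    }
  }
  out <- list(value = value, ok = TRUE)
  if (gradient) {
    out$grad_p0 <- g_p0
    out$grad_r <- g_r
  }
  out
}

#' Weighted residuals and their Jacobian
#'
#' The residual vector \eqn{(y_{ij} - g(x_i(t_j)))/\sigma_{ij}} whose
#' squared norm is [chi2_ml()], together with its Jacobian with respect
#' to the log10 reference parameters and the requested free
#' fold-changes. This is the interface used by the Levenberg-Marquardt
#' fits.
#'
#' @param problem an `fr_problem`.
#' @param log_p0 named log10 reference parameters.
#' @param r named log10 fold-changes (missing entries are zero).
#' @param free_r fold-change names to include as Jacobian columns.
#' @param jacobian compute the Jacobian?
#' @return list with `res`, `jac` (rows = residuals, columns =
#'   `c(parameters, free_r)`), and `ok`.
#' @export
chi2_residuals <- function(problem, log_p0, r = NULL,
                           free_r = problem$penalized, jacobian = TRUE) {
  model <- problem$model
  rfull <- stats::setNames(rep(0, length(problem$penalized)), problem$penalized)
  if (!is.null(r)) rfull[names(r)] <- r
  np <- length(model$param_names)
  nc <- np + length(free_r)
  if (!is.null(problem$fastplan)) {
    p0n <- 10^unname(log_p0[model$param_names])
    lp1 <- map_celltype_params(log_p0, rfull, 1L)
    p1n <- 10^unname(lp1[model$param_names])
    out <- hillnet_obj_cpp(model$net, p0n, p1n, model$x0(p0n),
                           problem$fastplan, jacobian,
                           model$control$rtol, model$control$atol,
                           as.integer(model$control$max_steps),
                           as.integer(model$control$order %||% 5L),
                           rows = TRUE)
    if (!isTRUE(out$ok)) return(list(res = NULL, jac = NULL, ok = FALSE))
    J <- NULL
    if (jacobian) {
      J <- matrix(0, length(out$res), nc)
      J[, seq_len(np)] <- out$rowjac
      if (length(free_r)) {
        ct1 <- out$row_ct == 1L
        J[ct1, np + seq_along(free_r)] <-
          out$rowjac[ct1, match(free_r, model$param_names), drop = FALSE]
      }
    }
    return(list(res = out$res, jac = J, ok = TRUE))
  }
  res_list <- list()
  jac_list <- list()
  for (grp in problem$groups) {
    lp <- map_celltype_params(log_p0, rfull, grp$cell_type)
    traj <- simulate_model(grp$pmodel, lp, grp$times, sens = jacobian)
    if (!traj$ok) return(list(res = NULL, jac = NULL, ok = FALSE))
    xi <- traj$states[cbind(grp$t_idx, grp$s_idx)]
    gi <- xi
    is_log <- grp$transform == "log10"
    if (any(is_log)) {
      if (any(xi[is_log] <= 0)) return(list(res = NULL, jac = NULL, ok = FALSE))
      gi[is_log] <- log10(xi[is_log])
    }
    res_list[[length(res_list) + 1]] <- (grp$y - gi) / grp$sd
    if (jacobian) {
      nt <- length(grp$times)
      ns <- length(model$state_names)
      dg_fac <- ifelse(is_log, 1 / (xi * log(10)), 1)
      Sm <- matrix(traj$sens, nrow = nt * ns)
      B <- (-dg_fac / grp$sd) *
        Sm[grp$t_idx + (grp$s_idx - 1) * nt, , drop = FALSE]
      J <- matrix(0, nrow(B), nc)
      J[, seq_len(np)] <- B
      if (grp$cell_type == 1L && length(free_r))
        J[, np + seq_along(free_r)] <- B[, match(free_r, model$param_names),
                                         drop = FALSE]
      jac_list[[length(jac_list) + 1]] <- J
    }
  }
  list(res = unlist(res_list),
       jac = if (jacobian) do.call(rbind, jac_list),
       ok = TRUE)
}

# Levenberg-Marquardt least-squares fit (box-constrained) from one
# start. Intended for warm starts, where its local quadratic convergence
# reaches deep optima in few Jacobian evaluations; the evaluation budget
# is bounded so it cannot thrash far from an optimum.
lm_fit_one <- function(problem, free_r, x0, lower, upper, maxiter = 30L) {
  np <- length(problem$model$param_names)
  res_fn <- function(x) {
    pr <- unpack_par(problem, x, free_r)
    out <- chi2_residuals(problem, pr$log_p0, pr$r, free_r, jacobian = FALSE)
    if (!out$ok) return(rep(1e6, nrow(problem$measurements)))
    out$res
  }
  jac_fn <- function(x) {
    pr <- unpack_par(problem, x, free_r)
    out <- chi2_residuals(problem, pr$log_p0, pr$r, free_r, jacobian = TRUE)
    if (!out$ok) return(matrix(0, nrow(problem$measurements),
                               np + length(free_r)))
    out$jac
  }
  res <- try(suppressWarnings(minpack.lm::nls.lm(
    pmin(pmax(x0, lower), upper), lower = lower, upper = upper,
    fn = res_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         maxfev = 4L * maxiter,
                                         ftol = 1e-10, ptol = 1e-10))),
    silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  v <- res$deviance
  if (!is.finite(v) || v >= 1e11) return(NULL)
  list(par = res$par, value = v, convergence = res$info,
       counts = c("function" = res$niter))
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# L-BFGS-B evaluates the objective and its gradient at the same point;
# computing both in one pass (the sensitivity integration yields the
# value for free) and caching avoids a redundant plain simulation pass.
pair_fngr <- function(full_eval) {
  cache_x <- NULL
  cache <- NULL
  refresh <- function(x) {
    cache_x <<- x
    cache <<- full_eval(x)
  }
  list(fn = function(x) {
    refresh(x)
    cache$value
  },
  gr = function(x) {
    if (is.null(cache_x) || !identical(x, cache_x)) refresh(x)
    cache$gradient
  })
}

# Bounded multi-start local optimization (L-BFGS-B). `starts` is a matrix
# with one start per row. With several starts, each start first runs a
# shorter scouting search and only the best scout is polished to full
# iteration depth. Returns the best converged result.
multistart_optim <- function(starts, fn, gr, lower, upper,
                             maxit = 300L, factr = 1e7) {
  one_run <- function(x0, maxit) {
    # deterministic evaluation cap: pathological line searches are cut
    # off instead of burning unbounded time
    n_eval <- 0L
    max_eval <- 3L * maxit
    fn_c <- function(x) {
      n_eval <<- n_eval + 1L
      if (n_eval > max_eval) return(BIG_CHI2)
      fn(x)
    }
    gr_c <- function(x) {
      if (n_eval > max_eval) return(rep(0, length(x)))
      gr(x)
    }
    try(stats::optim(pmin(pmax(x0, lower), upper), fn_c, gr_c,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = maxit, factr = factr, lmm = 20)),
        silent = TRUE)
  }
  best <- NULL
  n_fail <- 0
  diag_msgs <- character()
  scout_it <- if (nrow(starts) > 1) max(25L, as.integer(maxit / 3)) else maxit
  for (s in seq_len(nrow(starts))) {
    res <- one_run(starts[s, ], scout_it)
    if (inherits(res, "try-error") || !is.finite(res$value)) {
      n_fail <- n_fail + 1
      if (inherits(res, "try-error"))
        diag_msgs <- c(diag_msgs, conditionMessage(attr(res, "condition")))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all ", nrow(starts), " optimizer starts failed: ",
         paste(unique(diag_msgs), collapse = "; "))
  if (scout_it < maxit) {
    polished <- one_run(best$par, maxit)
    if (!inherits(polished, "try-error") && is.finite(polished$value) &&
        polished$value <= best$value)
      best <- polished
  }
  best$n_failed_starts <- n_fail
  best
}

# Latin-hypercube start points within bounds, deterministic given seed.
lhs_starts <- function(n_starts, lower, upper, seed) {
  d <- length(lower)
  if (n_starts == 1L)
    return(matrix((lower + upper) / 2, nrow = 1))
  with_seed(seed, {
    u <- lhs::randomLHS(n_starts, d)
    sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  })
}

# Copy of the problem with modified integrator tolerances (applied to
# the model and every pre-perturbed per-condition model).
problem_with_control <- function(problem, rtol, atol, order = NULL) {
  patch <- function(m) {
    m$control$rtol <- rtol
    m$control$atol <- atol
    if (!is.null(order)) m$control$order <- order
    m
  }
  problem$model <- patch(problem$model)
  problem$groups <- lapply(problem$groups, function(grp) {
    grp$pmodel <- patch(grp$pmodel)
    grp
  })
  problem
}

# Loose-tolerance companion problem for scouting and penalized path
# steps, if configured (control$step1_rtol / step1_atol).
problem_loose <- function(problem) {
  rt <- problem$control$step1_rtol
  if (is.null(rt)) return(NULL)
  # the low-order embedded pair only wins at very loose tolerances;
  # tighter scanning tolerances use the 5(4) pair
  problem_with_control(problem, rt,
                       problem$control$step1_atol %||% (rt * 0.01),
                       order = if (rt >= 5e-5) 3L else 5L)
}

free_fold_names <- function(problem, mask) {
  setdiff(problem$penalized, union(problem$fixed_zero, mask))
}

problem_bounds <- function(problem, free_r) {
  model <- problem$model
  bl <- model$bounds[match(model$param_names, model$bounds$name), ]
  fb <- problem$fold_bounds[match(free_r, problem$fold_bounds$name), ]
  list(lower = c(bl$lower, fb$lower), upper = c(bl$upper, fb$upper))
}

unpack_par <- function(problem, x, free_r) {
  np <- length(problem$model$param_names)
  log_p0 <- stats::setNames(x[seq_len(np)], problem$model$param_names)
  r <- stats::setNames(rep(0, length(problem$penalized)), problem$penalized)
  if (length(free_r)) r[free_r] <- x[np + seq_along(free_r)]
  list(log_p0 = log_p0, r = r)
}

# Unpenalized fit with an optional additional zero mask on fold-changes.
# Smooth least-squares structure makes box-constrained
# Levenberg-Marquardt the default; a quasi-Newton (L-BFGS-B) route is
# kept as configuration and as fallback.
fit_unpenalized <- function(problem, mask = character(), starts,
                            maxit = NULL, factr = NULL, optimizer = NULL) {
  maxit <- maxit %||% problem$control$maxit
  factr <- factr %||% problem$control$factr
  free_r <- free_fold_names(problem, mask)
  b <- problem_bounds(problem, free_r)
  np <- length(problem$model$param_names)
  optimizer <- optimizer %||% problem$control$optimizer %||% "lbfgsb"
  best <- NULL
  if (optimizer == "lm") {
    n_fail <- 0
    for (s in seq_len(nrow(starts))) {
      res <- lm_fit_one(problem, free_r, starts[s, ], b$lower, b$upper,
                        maxiter = problem$control$lm_maxiter %||%
                          min(maxit, 40L))
      if (is.null(res)) { n_fail <- n_fail + 1; next }
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (!is.null(best)) best$n_failed_starts <- n_fail
  }
  if (is.null(best)) {
    # L-BFGS-B needs finite objective values: integration failures are
    # reported as a huge finite plateau the optimizer retreats from.
    fg <- pair_fngr(function(x) {
      pr <- unpack_par(problem, x, free_r)
      cc <- chi2_ml(problem, pr$log_p0, pr$r, gradient = TRUE)
      list(value = if (!is.finite(cc$value)) BIG_CHI2 else cc$value,
           gradient = c(cc$grad_p0, cc$grad_r[free_r]))
    })
    best <- multistart_optim(starts, fg$fn, fg$gr, b$lower, b$upper,
                             maxit, factr)
  }
  pr <- unpack_par(problem, best$par, free_r)
  structure(list(log_p0 = pr$log_p0, r = pr$r, value = best$value,
                 convergence = best$convergence,
                 iterations = unname(best$counts["function"]),
                 n_starts = nrow(starts),
                 n_failed_starts = best$n_failed_starts,
                 mask = union(problem$fixed_zero, mask),
                 problem = problem),
            class = "fr_fit")
}

#' Unpenalized maximum-likelihood fit
#'
#' Best-of-multi-start bounded quasi-Newton (L-BFGS-B) minimization of
#' [chi2_ml()] over the log10 reference parameters and the free
#' fold-changes. Start points are Latin-hypercube samples within the
#' bounds; fold-changes start at zero (the cell-type-independent null
#' model) for half of the starts. Deterministic given `seed`.
#'
#' @param problem an `fr_problem`.
#' @param n_starts number of local searches (default from the problem's
#'   control list).
#' @param seed integer seed for the start points.
#' @param mask additional fold-changes to hold at exactly zero.
#' @return an `fr_fit` with the estimated `log_p0`, `r`, the objective
#'   `value`, convergence metadata and the applied zero `mask`.
#' @export
fit_ml <- function(problem, n_starts = NULL, seed = 1L, mask = character()) {
  n_starts <- as.integer(n_starts %||% problem$control$n_starts)
  free_r <- free_fold_names(problem, mask)
  b <- problem_bounds(problem, free_r)
  starts <- lhs_starts(n_starts, b$lower, b$upper, seed)
  # fold-changes start at the sparse null (r = 0) for half of the starts
  np <- length(problem$model$param_names)
  if (length(free_r) && n_starts > 1L) {
    zero_rows <- seq_len(ceiling(n_starts / 2))
    starts[zero_rows, np + seq_along(free_r)] <- 0
  } else if (length(free_r)) {
    starts[, np + seq_along(free_r)] <- 0
  }
  # first start at the box centre with the cell-type-independent null
  if (length(free_r)) starts[1, ] <- c((b$lower + b$upper)[seq_len(np)] / 2,
                                       rep(0, length(free_r)))
  loose <- problem_loose(problem)
  if (is.null(loose) || n_starts == 1L)
    return(fit_unpenalized(problem, mask, starts))
  # Staged search: (A) fit the cell-type-independent null model (all
  # fold-changes masked; a much easier landscape) from every start at
  # loose integrator tolerance, (B) scout the full model warm-started
  # from the best null fit plus the remaining starts, (C) polish the
  # best scout at the accurate tolerance.
  scout_maxit <- problem$control$scout_maxit %||% 60L
  np <- length(problem$model$param_names)
  null_best <- try(fit_unpenalized(loose, problem$penalized,
                                   starts[1, seq_len(np), drop = FALSE],
                                   maxit = 40L), silent = TRUE)
  if (inherits(null_best, "try-error")) null_best <- NULL
  # triage: short runs from several starts, then longer scouting from
  # the two most promising basins
  triage_starts <- lhs_starts(max(2L * n_starts, 2L),
                              b$lower, b$upper, seed + 1L)
  triage_starts[, np + seq_along(free_r)] <- 0
  triage_starts[1, ] <- c((b$lower + b$upper)[seq_len(np)] / 2,
                          rep(0, length(free_r)))
  if (!is.null(null_best))
    triage_starts[2, ] <- c(null_best$log_p0, rep(0, length(free_r)))
  triaged <- list()
  for (s in seq_len(nrow(triage_starts))) {
    sc <- try(fit_unpenalized(loose, mask,
                              triage_starts[s, , drop = FALSE],
                              maxit = 25L), silent = TRUE)
    if (inherits(sc, "try-error")) next
    triaged[[length(triaged) + 1]] <- sc
  }
  best <- NULL
  if (length(triaged)) {
    ord <- order(vapply(triaged, `[[`, numeric(1), "value"))
    for (s in ord[seq_len(min(2L, length(ord)))]) {
      sf <- triaged[[s]]
      sc <- try(fit_unpenalized(loose, mask,
                                matrix(c(sf$log_p0, sf$r[free_r]), nrow = 1),
                                maxit = scout_maxit), silent = TRUE)
      if (inherits(sc, "try-error")) next
      if (is.null(best) || sc$value < best$value) best <- sc
    }
  }
  if (is.null(best)) return(fit_unpenalized(problem, mask, starts))
  # polish the best basin at the accurate tolerance; warm-started
  # Levenberg-Marquardt first, quasi-Newton if it goes nowhere
  ml_maxit <- problem$control$ml_maxit %||% problem$control$maxit
  st_best <- matrix(c(best$log_p0, best$r[free_r]), nrow = 1)
  polished <- fit_unpenalized(problem, mask, st_best, maxit = ml_maxit,
                              optimizer = "lm")
  check <- chi2_ml(problem, best$log_p0, best$r)$value
  if (!is.finite(polished$value) || polished$value > check) {
    alt <- fit_unpenalized(problem, mask, st_best, maxit = ml_maxit)
    if (alt$value < polished$value) polished <- alt
  }
  polished$n_starts <- n_starts
  polished
}

#' @export
print.fr_fit <- function(x, ...) {
  cat("<fr_fit> chi2 =", format(x$value, digits = 6),
      "| nonzero fold-changes:", sum(abs(x$r) > 1e-10), "/", length(x$r), "\n")
  invisible(x)
}

#' Tidy parameter estimates of a fit
#'
#' @param x an `fr_fit`.
#' @param ... unused.
#' @return tibble with columns `parameter`, `type` (`"reference"` or
#'   `"fold_change"`), `estimate` (log10 scale) and `masked`.
#' @export
tidy.fr_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(parameter = names(x$log_p0), type = "reference",
                   estimate = unname(x$log_p0), masked = FALSE),
    tibble::tibble(parameter = names(x$r), type = "fold_change",
                   estimate = unname(x$r),
                   masked = names(x$r) %in% x$mask))
}

#' One-line fit summary
#'
#' @param x an `fr_fit`.
#' @param ... unused.
#' @return one-row tibble with the objective value, convergence code,
#'   iteration count and the sizes of the parameter blocks.
#' @export
glance.fr_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$value, convergence = x$convergence,
                 iterations = x$iterations, n_starts = x$n_starts,
                 n_fold_changes = length(x$r),
                 n_nonzero = sum(abs(x$r) > 1e-10),
                 n_masked = length(x$mask))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

BIG_CHI2 <- 1e12
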