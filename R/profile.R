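# Build the pinned re-optimization used by profiling: one coordinate
# (reference parameter, or fold-change addressed as "r_<name>") is held
# fixed while all remaining free coordinates are re-optimized.
profile_machinery <- function(problem, mask, parameter) {
  model <- problem$model
  free_r <- free_fold_names(problem, mask)
  p_ids <- model$param_names
  r_ids <- paste0("r_", free_r)
  ids <- c(p_ids, r_ids)
  if (!parameter %in% ids)
    stop("unknown or fixed parameter '", parameter, "'; fold-changes are ",
         "addressed as 'r_<parameter>'")
  j <- match(parameter, ids)
  b <- problem_bounds(problem, free_r)
  np <- length(p_ids)
  eval_chi2 <- function(full, gradient = FALSE) {
    log_p0 <- stats::setNames(full[seq_len(np)], p_ids)
    r <- stats::setNames(rep(0, length(problem$penalized)), problem$penalized)
    if (length(free_r)) r[free_r] <- full[np + seq_along(free_r)]
    chi2_ml(problem, log_p0, r, gradient = gradient)
  }
  list(ids = ids, j = j, lower = b$lower, upper = b$upper, np = np,
       free_r = free_r, eval_chi2 = eval_chi2)
}

profile_refit <- function(mach, value, start_full, maxit, factr) {
  j <- mach$j
  fg <- pair_fngr(function(x) {
    full <- append(x, value, after = j - 1)
    cc <- mach$eval_chi2(full, gradient = TRUE)
    g <- c(cc$grad_p0, cc$grad_r[mach$free_r])
    list(value = if (!is.finite(cc$value)) BIG_CHI2 else cc$value,
         gradient = g[-j])
  })
  res <- try(stats::optim(start_full[-j], fg$fn, fg$gr, method = "L-BFGS-B",
                          lower = mach$lower[-j], upper = mach$upper[-j],
                          control = list(maxit = maxit, factr = factr)),
             silent = TRUE)
  if (inherits(res, "try-error") || !is.finite(res$value)) return(NULL)
  list(chi2 = res$value, full = append(res$par, value, after = j - 1))
}

#' Profile likelihood of one parameter
#'
#' Re-optimizes \eqn{\chi^2_{ML}} over all remaining free parameters for
#' a sequence of fixed values of the profiled parameter, stepping
#' outwards from the optimum in both directions and warm-starting every
#' re-optimization from its neighbour. Step sizes adapt towards a target
#' objective increase of about 0.2 per step; profiling stops once the
#' profile rises one unit above the confidence threshold, the parameter
#' bound is reached, or `max_steps` steps were taken per direction.
#'
#' Reference parameters are addressed by name, fold-changes as
#' `"r_<name>"` (fold-changes already masked to zero in the fit cannot
#' be profiled).
#'
#' @param problem an `fr_problem`.
#' @param fit a converged `fr_fit` (the profile's anchor).
#' @param parameter coordinate to profile.
#' @param grid optional explicit grid of values to profile on instead of
#'   adaptive stepping.
#' @param alpha confidence level used for the stopping rule and the
#'   reported interval.
#' @param control list: `dchi2_step` (target objective increase per
#'   step, default 0.2), `h0` (initial step, default 0.05 log10 units),
#'   `max_steps` (per direction, default 100), `maxit`, `factr`.
#' @return an `fr_profile`: grid tibble (`value`, `chi2`), the
#'   minimum, and the confidence interval with open-end flags.
#' @export
profile_likelihood <- function(problem, fit, parameter, grid = NULL,
                               alpha = 0.95, control = list()) {
  ctrl <- utils::modifyList(list(dchi2_step = 0.2, h0 = 0.05,
                                 max_steps = 100L,
                                 maxit = problem$control$maxit,
                                 factr = problem$control$factr),
                            control)
  mach <- profile_machinery(problem, fit$mask, parameter)
  start_full <- c(fit$log_p0[problem$model$param_names],
                  fit$r[mach$free_r])
  est <- unname(start_full[mach$j])
  thr <- chi2_quantile(alpha, 1)

  pts <- list(tibble::tibble(value = est, chi2 = fit$value))
  if (!is.null(grid)) {
    for (side in c(-1, 1)) {
      vals <- if (side < 0) rev(grid[grid < est]) else grid[grid > est]
      cur <- start_full
      for (v in vals) {
        res <- profile_refit(mach, v, cur, ctrl$maxit, ctrl$factr)
        if (is.null(res)) next
        pts[[length(pts) + 1]] <- tibble::tibble(value = v, chi2 = res$chi2)
        cur <- res$full
      }
    }
  } else {
    for (side in c(-1, 1)) {
      cur <- start_full
      v <- est
      h <- ctrl$h0
      last_chi2 <- fit$value
      for (s in seq_len(ctrl$max_steps)) {
        at_bound <- FALSE
        v_next <- v + side * h
        lo <- mach$lower[mach$j]; hi <- mach$upper[mach$j]
        if (v_next <= lo) { v_next <- lo; at_bound <- TRUE }
        if (v_next >= hi) { v_next <- hi; at_bound <- TRUE }
        res <- profile_refit(mach, v_next, cur, ctrl$maxit, ctrl$factr)
        if (is.null(res)) break
        pts[[length(pts) + 1]] <- tibble::tibble(value = v_next,
                                                 chi2 = res$chi2)
        dchi <- abs(res$chi2 - last_chi2)
        h <- h * min(3, max(1 / 3, sqrt(ctrl$dchi2_step / max(dchi, 1e-3))))
        cur <- res$full
        v <- v_next
        last_chi2 <- res$chi2
        if (at_bound || res$chi2 - fit$value > thr + 1) break
      }
    }
  }
  grid_tbl <- dplyr::arrange(dplyr::bind_rows(pts), .data$value)
  chi2_min <- min(fit$value, grid_tbl$chi2)
  out <- structure(list(parameter = parameter, estimate = est,
                        grid = grid_tbl, chi2_min = chi2_min,
                        alpha = alpha,
                        bounds = c(mach$lower[mach$j], mach$upper[mach$j])),
                   class = "fr_profile")
  out$ci <- confidence_interval(out, alpha)
  out
}

#' Profile-based confidence interval
#'
#' The level-`alpha` interval is the set of profiled values whose
#' objective stays within \eqn{q_\alpha^{(1)}} of the minimum; crossing
#' points are located by linear interpolation between grid points. An
#' end that never crosses the threshold inside the parameter bounds is
#' flagged open (practical non-identifiability).
#'
#' @param profile an `fr_profile`.
#' @param alpha confidence level.
#' @return tibble with `lower`, `upper`, `lower_open`, `upper_open`.
#' @export
confidence_interval <- function(profile, alpha = 0.95) {
  thr <- chi2_quantile(alpha, 1)
  g <- profile$grid
  d <- g$chi2 - profile$chi2_min
  est <- profile$estimate
  cross <- function(side) {
    idx <- if (side < 0) which(g$value <= est) else which(g$value >= est)
    if (side < 0) idx <- rev(idx)
    # walk outward; find first grid interval straddling the threshold
    for (k in seq_along(idx)[-1]) {
      i0 <- idx[k - 1]; i1 <- idx[k]
      if (d[i0] <= thr && d[i1] > thr) {
        f <- (thr - d[i0]) / (d[i1] - d[i0])
        return(list(bound = g$value[i0] + f * (g$value[i1] - g$value[i0]),
                    open = FALSE))
      }
    }
    list(bound = if (side < 0) min(g$value) else max(g$value), open = TRUE)
  }
  lo <- cross(-1)
  hi <- cross(1)
  tibble::tibble(lower = lo$bound, upper = hi$bound,
                 lower_open = lo$open, upper_open = hi$open)
}

#' @export
print.fr_profile <- function(x, ...) {
  cat("<fr_profile>", x$parameter, "estimate =", format(x$estimate, digits = 4),
      "\n  ", 100 * x$alpha, "% CI [", format(x$ci$lower, digits = 4),
      if (x$ci$lower_open) "(open)" else "", ", ",
      format(x$ci$upper, digits = 4),
      if (x$ci$upper_open) "(open)" else "", "]\n")
  invisible(x)
}

#' @export
tidy.fr_profile <- function(x, ...) {
  dplyr::mutate(x$grid, parameter = x$parameter,
                delta_chi2 = .data$chi2 - x$chi2_min)
}

#' @export
glance.fr_profile <- function(x, ...) {
  dplyr::mutate(x$ci, parameter = x$parameter, estimate = x$estimate,
                alpha = x$alpha, chi2_min = x$chi2_min)
}

#' Plot a likelihood profile
#'
#' @param object an `fr_profile`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fr_profile <- function(object, ...) {
  thr <- chi2_quantile(object$alpha, 1)
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(.data$value, .data$chi2 - object$chi2_min)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = 3) +
    ggplot2::labs(x = object$parameter, y = "profile chi2 - min")
}

#' Two-dimensional profile-likelihood grid
#'
#' Diagnostic landscape over two parameters: both are fixed on a grid
#' while all remaining free parameters are re-optimized (warm-started
#' along each row). No refinement beyond the grid is attempted.
#'
#' @param problem an `fr_problem`.
#' @param fit anchor `fr_fit`.
#' @param parameters character vector of two coordinate ids.
#' @param grid1,grid2 numeric grids for the two coordinates.
#' @param control as in [profile_likelihood()].
#' @return tibble with columns `v1`, `v2`, `chi2`.
#' @export
profile_likelihood_2d <- function(problem, fit, parameters, grid1, grid2,
                                  control = list()) {
  stopifnot(length(parameters) == 2)
  ctrl <- utils::modifyList(list(maxit = problem$control$maxit,
                                 factr = problem$control$factr), control)
  mach1 <- profile_machinery(problem, fit$mask, parameters[1])
  mach2 <- profile_machinery(problem, fit$mask, parameters[2])
  j1 <- mach1$j; j2 <- mach2$j
  stopifnot(j1 != j2)
  start0 <- c(fit$log_p0[problem$model$param_names], fit$r[mach1$free_r])
  out <- list()
  for (v1 in grid1) {
    cur <- start0
    cur[j1] <- v1
    for (v2 in grid2) {
      cur[j2] <- v2
      # pin both coordinates: profile the second with the first fixed
      machp <- mach2
      fn <- function(x) {
        full <- append(x, v2, after = j2 - 1)
        full[j1] <- v1
        v <- machp$eval_chi2(full)$value
        if (!is.finite(v)) BIG_CHI2 else v
      }
      gr <- function(x) {
        full <- append(x, v2, after = j2 - 1)
        full[j1] <- v1
        cc <- machp$eval_chi2(full, gradient = TRUE)
        g <- c(cc$grad_p0, cc$grad_r[machp$free_r])
        g[j1] <- 0
        g[-j2]
      }
      res <- try(stats::optim(cur[-j2], fn, gr, method = "L-BFGS-B",
                              lower = machp$lower[-j2],
                              upper = machp$upper[-j2],
                              control = list(maxit = ctrl$maxit,
                                             factr = ctrl$factr)),
                 silent = TRUE)
      chi2 <- if (inherits(res, "try-error")) NA_real_ else res$value
      if (!inherits(res, "try-error")) {
        cur <- append(res$par, v2, after = j2 - 1)
        cur[j1] <- v1
      }
      out[[length(out) + 1]] <- tibble::tibble(v1 = v1, v2 = v2, chi2 = chi2)
    }
  }
  dplyr::bind_rows(out)
}
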