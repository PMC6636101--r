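#' Zero set of a fold-change vector
#'
#' Indices (or names, when `r` is named) of the fold-changes that count
#' as zero: \eqn{|r_i - target| \le \epsilon}, with the boundary
#' included. The same cut-off is used for every penalty family.
#'
#' @param r fold-change vector.
#' @param epsilon zero cut-off (default `1e-10`).
#' @param target centre (default 0).
#' @return character vector of names if `r` is named, else integer
#'   indices.
#' @export
zero_set <- function(r, epsilon = 1e-10, target = 0) {
  idx <- which(abs(r - target) <= epsilon)
  if (!is.null(names(r))) names(r)[idx] else idx
}

#' Quantile of the chi-square distribution
#'
#' Threshold \eqn{q_\alpha^{(m)}} used both for profile-likelihood
#' confidence intervals and for the likelihood-ratio selection along the
#' penalty scan.
#'
#' @param alpha probability level in (0, 1).
#' @param m degrees of freedom (>= 1).
#' @return the quantile.
#' @export
chi2_quantile <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  stats::qchisq(alpha, df = m)
}

#' Likelihood-ratio statistic of a shrunk model
#'
#' \eqn{D(\lambda) = \chi^2(\lambda) - \chi^2(0)}: the objective-function
#' cost of forcing the zero set to zero. Small negative values caused by
#' optimizer noise are clamped at 0; values below -0.01 additionally
#' raise a warning because they indicate the unpenalized baseline fit
#' was not at its optimum.
#'
#' @param chi2_lambda refit objective at penalty strength lambda.
#' @param chi2_zero unpenalized baseline objective.
#' @return the clamped difference.
#' @export
lrt_statistic <- function(chi2_lambda, chi2_zero) {
  stopifnot(is.finite(chi2_lambda), is.finite(chi2_zero))
  d <- chi2_lambda - chi2_zero
  if (d < -0.01)
    warning("restricted refit beats the unpenalized baseline by ",
            format(-d), "; baseline fit was likely trapped")
  max(d, 0)
}

#' Default penalty-strength grid
#'
#' Log-spaced grid from `1e-4` to `1e6` (41 points by default).
#'
#' @param n_lambda number of grid points.
#' @param lambda_min,lambda_max grid end points.
#' @return ascending numeric vector.
#' @export
default_lambda_grid <- function(n_lambda = 41, lambda_min = 1e-4,
                                lambda_max = 1e6) {
  10^seq(log10(lambda_min), log10(lambda_max), length.out = n_lambda)
}

# Proximal operator of t * lambda * nu(.) per family, applied
# coordinate-wise to the fold-change block. The non-convex lq penalty is
# majorized by its local linearization (the clamped gradient), i.e.
# reweighted soft thresholding.
prox_r <- function(spec, lambda, t, r, weights = NULL) {
  s <- r - spec$target
  th <- switch(spec$family,
               l1 = t * lambda,
               lq = t * lambda * spec$q * pmax(abs(s), spec$epsilon)^(spec$q - 1),
               elastic_net = t * lambda * (1 - spec$alpha),
               adaptive_lasso = t * lambda * weights)
  out <- sign(s) * pmax(abs(s) - th, 0)
  if (spec$family == "elastic_net")
    out <- out / (1 + 2 * t * lambda * spec$alpha)
  spec$target + out
}

# Monotone proximal-gradient polish of the penalized objective: descent
# steps on the smooth likelihood plus an exact (or majorized) proximal
# step on the penalty. Quasi-Newton line searches can stall at the
# penalty kinks when warm-started near an optimum; thresholding moves
# coordinates onto exact zeros regardless.
prox_polish <- function(problem, spec, lambda, log_p0, r, free_r,
                        niter = 25L, weights = NULL) {
  b <- problem_bounds(problem, free_r)
  np <- length(log_p0)
  lo_p <- b$lower[seq_len(np)]; hi_p <- b$upper[seq_len(np)]
  lo_r <- b$lower[np + seq_along(free_r)]
  hi_r <- b$upper[np + seq_along(free_r)]
  pen <- function(rr) penalty_value(spec, rr[free_r])
  cc <- chi2_ml(problem, log_p0, r, gradient = TRUE)
  if (!is.finite(cc$value)) return(list(log_p0 = log_p0, r = r))
  Fcur <- cc$value + lambda * pen(r)
  t <- 0.2
  for (it in seq_len(niter)) {
    ok_step <- FALSE
    for (bt in 1:9) {
      cand_p0 <- pmin(pmax(log_p0 - t * cc$grad_p0, lo_p), hi_p)
      rr <- r
      rr[free_r] <- pmin(pmax(
        prox_r(spec, lambda, t, r[free_r] - t * cc$grad_r[free_r], weights),
        lo_r), hi_r)
      vc <- chi2_ml(problem, cand_p0, rr)$value
      if (is.finite(vc) && vc + lambda * pen(rr) < Fcur - 1e-12) {
        ok_step <- TRUE
        break
      }
      t <- t / 4
    }
    if (!ok_step) break
    log_p0 <- cand_p0
    r <- rr
    Fnew <- vc + lambda * pen(rr)
    converged <- Fcur - Fnew < 1e-4 * max(1, abs(Fnew))
    Fcur <- Fnew
    cc <- chi2_ml(problem, log_p0, r, gradient = TRUE)
    if (!is.finite(cc$value) || converged) break
    t <- t * 2
  }
  list(log_p0 = log_p0, r = r, value = Fcur)
}

# Penalized fit at one lambda. Each free fold-change is split into
# nonnegative halves r = target + sp - sm so the L-BFGS-B active set can
# put coordinates exactly at zero; for complementary (sp, sm) the split
# penalty equals the family's definition, and the lq gradient uses the
# epsilon clamp so it stays finite at the origin.
fit_penalized <- function(problem, spec, lambda, start,
                          maxit = NULL, factr = NULL) {
  maxit <- maxit %||% problem$control$step1_maxit %||% problem$control$maxit
  factr <- factr %||% problem$control$step1_factr %||% problem$control$factr
  free_r <- free_fold_names(problem, character())
  nfr <- length(free_r)
  np <- length(problem$model$param_names)
  b <- problem_bounds(problem, free_r)
  tgt <- rep_len(spec$target, nfr)
  up_sp <- pmax(0, b$upper[np + seq_len(nfr)] - tgt)
  up_sm <- pmax(0, tgt - b$lower[np + seq_len(nfr)])
  lower <- c(b$lower[seq_len(np)], rep(0, 2 * nfr))
  upper <- c(b$upper[seq_len(np)], up_sp, up_sm)
  w <- if (spec$family == "adaptive_lasso") {
    spec_weights(spec, stats::setNames(rep(0, nfr), free_r))
  } else NULL

  split_r <- function(x) {
    sp <- x[np + seq_len(nfr)]
    sm <- x[np + nfr + seq_len(nfr)]
    list(sp = sp, sm = sm,
         r = stats::setNames(tgt + sp - sm, free_r), m = sp + sm)
  }
  pen_value <- function(m) {
    switch(spec$family,
           l1 = sum(m),
           lq = sum(m^spec$q),
           elastic_net = (1 - spec$alpha) * sum(m) + spec$alpha * sum(m^2),
           adaptive_lasso = sum(w * m))
  }
  fg <- pair_fngr(function(x) {
    s <- split_r(x)
    pr <- unpack_par(problem, c(x[seq_len(np)]), character())
    cc <- chi2_ml(problem, pr$log_p0, s$r, gradient = TRUE)
    dmag <- lambda * penalty_dmag(spec, s$m, w)
    gre <- cc$grad_r[free_r]
    list(value = if (!is.finite(cc$value)) BIG_CHI2 else
           cc$value + lambda * pen_value(s$m),
         gradient = c(cc$grad_p0, gre + dmag, -gre + dmag))
  })

  s0 <- start$r[free_r] - tgt
  x0 <- c(start$log_p0[problem$model$param_names], pmax(s0, 0), pmax(-s0, 0))
  best <- multistart_optim(matrix(x0, nrow = 1), fg$fn, fg$gr, lower, upper,
                           maxit, factr)
  s <- split_r(best$par)
  log_p0 <- stats::setNames(best$par[seq_len(np)],
                            problem$model$param_names)
  r <- stats::setNames(rep(spec$target, length(problem$penalized)),
                       problem$penalized)
  r[problem$fixed_zero] <- 0
  r[free_r] <- s$r
  value <- best$value
  # proximal polish: walks coordinates onto exact zeros where the
  # quasi-Newton line search stalls at the penalty kinks; skipped while
  # the penalty term is still negligible
  if (lambda * penalty_value(spec, r[free_r]) > 0.05) {
    pp <- prox_polish(problem, spec, lambda, log_p0, r, free_r,
                      niter = problem$control$prox_iter %||% 25L,
                      weights = w)
    if (!is.null(pp$value) && is.finite(pp$value) && pp$value < value) {
      log_p0 <- pp$log_p0
      r <- pp$r
      value <- pp$value
    }
  }
  structure(list(log_p0 = log_p0,
                 r = r, value = value,
                 chi2 = value - lambda * penalty_value(spec, r[free_r]),
                 convergence = best$convergence,
                 iterations = unname(best$counts["function"]),
                 n_starts = 1L, n_failed_starts = 0L,
                 mask = problem$fixed_zero, lambda = lambda, spec = spec,
                 problem = problem),
            class = "fr_fit")
}

strip_fit <- function(fit) {
  fit$problem <- NULL
  fit
}

#' Two-step regularization scan over penalty strengths
#'
#' For each `lambda` of the ascending grid: (step 1) minimize the
#' penalized objective \eqn{\chi^2_{ML} + \lambda\nu(r)}, warm-started
#' from the previous grid point so the scan follows one solution branch
#' and is not trapped in the artefactual lq optimum at zero; read off the
#' zero set \eqn{Z(\lambda)} (`|r_i| <= epsilon`); (step 2) refit without
#' penalty with \eqn{Z(\lambda)} fixed to zero, removing the shrinkage
#' bias. The likelihood-ratio statistic \eqn{D(\lambda) = \chi^2(\lambda)
#' - \chi^2(0)} is compared against \eqn{q_\alpha^{\#Z(\lambda)}} and the
#' parsimonious model sits at the largest admissible `lambda`.
#'
#' Since any refit with a zero mask is a restriction of the full model,
#' the baseline \eqn{\chi^2(0)} is taken as the minimum over the
#' unpenalized fit and all step-2 refits, which protects the statistic
#' against a trapped baseline optimum. Step-2 refits are cached by zero
#' set (the restricted problem does not depend on `lambda`), and once the
#' path is fully shrunk the remaining grid points reuse the saturated
#' solution.
#'
#' @param problem an `fr_problem`.
#' @param spec an [penalty_spec()]; adaptive-lasso weights are derived
#'   from the unpenalized fit when not supplied.
#' @param lambda_grid ascending penalty strengths.
#' @param alpha significance level of the likelihood-ratio selection.
#' @param seed seed for the multi-start unpenalized fit.
#' @param init_fit optional precomputed unpenalized `fr_fit` (shared
#'   across penalty families in studies).
#' @param refit_cache optional environment used to cache step-2 refits
#'   by zero set; pass one environment to several scans of the same
#'   problem to share identical restricted refits across penalty
#'   families.
#' @return an object of class `fr_regpath`; see [parsimonious_lambda()],
#'   [tidy.fr_regpath()], [glance.fr_regpath()], [autoplot.fr_regpath()].
#' @export
scan_lambda <- function(problem, spec, lambda_grid = default_lambda_grid(),
                        alpha = 0.95, seed = 1L, init_fit = NULL,
                        refit_cache = NULL) {
  stopifnot(!is.unsorted(lambda_grid), all(lambda_grid > 0))
  fit0 <- init_fit %||% fit_ml(problem, seed = seed)
  if (spec$family == "adaptive_lasso" && is.null(spec$weights))
    spec$weights <- adaptive_weights(fit0$r, spec$gamma, spec$epsilon)

  free_r <- free_fold_names(problem, character())
  n_free <- length(free_r)
  refit_cache <- refit_cache %||% new.env(parent = emptyenv())
  # When the problem configures a loose scanning tolerance
  # (control$step1_rtol), the whole lambda loop — penalized fits and
  # restricted refits — runs at that tolerance, and a descending
  # confirmation pass afterwards re-polishes the refits at the accurate
  # tolerance only around the admissibility boundary, where the
  # likelihood-ratio decision actually depends on them. Without a loose
  # tolerance everything below runs at the accurate tolerance and no
  # confirmation is needed.
  ploose <- problem_loose(problem)
  two_phase <- !is.null(ploose)
  pscan <- ploose %||% problem
  scan_maxit <- if (two_phase) problem$control$refit_scout %||% 80L else NULL
  chi2_fit0_scan <- if (two_phase)
    chi2_ml(pscan, fit0$log_p0, fit0$r)$value else fit0$value

  # Restricted refits are warm-started, which is Levenberg-Marquardt
  # territory: deep convergence in few Jacobian evaluations (with a
  # quasi-Newton fallback inside fit_unpenalized when it fails).
  refit_for_mask <- function(Z, start_fits, prob, maxit, prefix) {
    key <- paste0(prefix, paste(sort(Z), collapse = "|"))
    hit <- refit_cache[[key]]
    if (!is.null(hit)) return(hit)
    if (inherits(start_fits, "fr_fit")) start_fits <- list(start_fits)
    rf <- NULL
    for (sf in start_fits) {
      start_r <- sf$r
      start_r[Z] <- 0
      st <- matrix(c(sf$log_p0, start_r[setdiff(free_r, Z)]), nrow = 1)
      cand <- try(fit_unpenalized(prob, mask = Z, starts = st,
                                  maxit = maxit, optimizer = "lm"),
                  silent = TRUE)
      if (inherits(cand, "try-error")) next
      if (is.null(rf) || cand$value < rf$value) rf <- cand
    }
    if (is.null(rf)) return(NULL)
    refit_cache[[key]] <- rf
    rf
  }

  # reference value of the fully shrunk model: used to decide when a
  # zero-start candidate is worth adding to the warm-started branch
  null_fit <- if (length(free_r))
    refit_for_mask(problem$penalized, fit0, pscan, scan_maxit, "S:") else NULL
  null_value <- if (is.null(null_fit)) Inf else null_fit$value

  prev <- fit0
  saturated <- NULL
  rows <- vector("list", length(lambda_grid))

  for (k in seq_along(lambda_grid)) {
    lam <- lambda_grid[k]
    if (!is.null(saturated)) {
      rows[[k]] <- utils::modifyList(saturated,
                                     list(lambda = lam, t_step1 = 0,
                                          t_step2 = 0))
      next
    }
    t0 <- proc.time()[["elapsed"]]
    # while the penalty term is negligible against the likelihood the
    # penalized optimum coincides with the unpenalized one: carry the
    # previous estimate forward instead of re-optimizing (the +1 floor
    # keeps the shortcut from firing at large lambda when the current
    # fold-changes happen to be near zero)
    pen_prev <- lam * (penalty_value(spec, prev$r) + 1)
    if (pen_prev < (problem$control$quiet_tol %||% 0.02)) {
      step1 <- prev
    } else {
    # once the penalty term is non-negligible the penalized optimizer
    # must walk many coordinates to their bounds, which needs more
    # iterations than the quiet region before shrinkage sets in
    active <- pen_prev > 1
    maxit1 <- if (active)
      problem$control$step1_active_maxit %||% 80L else NULL
    step1 <- try(fit_penalized(pscan, spec, lam, prev, maxit = maxit1),
                 silent = TRUE)
    }
    # Second candidate: the fully shrunk start. The warm-started branch
    # protects against the artefactual lq optimum at zero; comparing
    # with a zero-start branch (tried once shrinkage is active or the
    # warm branch is beaten by the fully shrunk model) protects against
    # a warm path that cannot reach the shrunk optimum at strong
    # penalization.
    if (!inherits(step1, "try-error")) {
      if (step1$value > null_value) {
        zstart <- list(log_p0 = step1$log_p0,
                       r = stats::setNames(rep(0, length(problem$penalized)),
                                           problem$penalized))
        alt <- try(fit_penalized(pscan, spec, lam, zstart), silent = TRUE)
        if (!inherits(alt, "try-error") && alt$value < step1$value)
          step1 <- alt
      }
    }
    t_step1 <- proc.time()[["elapsed"]] - t0
    if (inherits(step1, "try-error")) {
      rows[[k]] <- list(lambda = lam, ok = FALSE, zero = list(character()),
                        n_zero = NA_integer_, chi2 = NA_real_,
                        fit1 = list(NULL), refit = list(NULL),
                        t_step1 = t_step1, t_step2 = 0)
      next
    }
    prev <- step1
    Z <- zero_set(step1$r, spec$epsilon)
    t0 <- proc.time()[["elapsed"]]
    refit <- if (length(Z) == 0) {
      if (two_phase) list(value = chi2_fit0_scan, fit = fit0) else
        list(value = fit0$value, fit = fit0)
    } else {
      rf <- refit_for_mask(Z, list(step1, fit0), pscan, scan_maxit, "S:")
      if (is.null(rf)) NULL else list(value = rf$value, fit = rf)
    }
    if (is.null(refit)) {
      rows[[k]] <- list(lambda = lam, ok = FALSE, zero = list(Z),
                        n_zero = length(Z), chi2 = NA_real_,
                        fit1 = list(strip_fit(step1)), refit = list(NULL),
                        t_step1 = t_step1, t_step2 = 0)
      next
    }
    rows[[k]] <- list(lambda = lam, ok = TRUE, zero = list(Z),
                      n_zero = length(Z), chi2 = refit$value,
                      fit1 = list(strip_fit(step1)),
                      refit = list(strip_fit(refit$fit)),
                      t_step1 = t_step1,
                      t_step2 = proc.time()[["elapsed"]] - t0)
    if (length(Z) == length(problem$penalized))
      saturated <- rows[[k]]
  }

  path <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  chi2_0 <- min(chi2_fit0_scan, path$chi2[path$ok], na.rm = TRUE)
  path$D <- ifelse(path$ok, pmax(path$chi2 - chi2_0, 0), NA_real_)
  path$threshold <- ifelse(path$n_zero >= 1,
                           stats::qchisq(alpha, df = pmax(path$n_zero, 1)),
                           Inf)
  # strengths without shrinkage are admissible by definition, but only
  # in the region before shrinkage sets in: an empty zero set above the
  # onset is an optimizer artefact, not a sparser model
  pre_onset <- !cumsum(ifelse(is.na(path$n_zero), 0, path$n_zero) > 0)
  path$admissible <- path$ok & ((path$n_zero == 0 & pre_onset) |
                                  (path$n_zero > 0 & path$D < path$threshold))
  path$refined <- !two_phase & path$ok

  out <- structure(list(path = path, chi2_0 = chi2_0, fit0 = fit0,
                        spec = spec, alpha = alpha, problem = problem,
                        lambda_grid = lambda_grid),
                   class = "fr_regpath")

  if (!two_phase) {
    sel <- parsimonious_lambda(out, alpha)
    out$lambda_star <- sel$lambda_star
    out$final_fit <- sel$fit
    out$positives <- sel$positives
    return(out)
  }

  # Confirmation pass: walk the loose-admissible candidates from the
  # largest lambda down, re-polishing each candidate's restricted refit
  # at the accurate tolerance, until one is admissible under the
  # accurate likelihood-ratio statistic.
  margin <- problem$control$confirm_margin %||% 10
  confirm_maxit <- problem$control$confirm_maxit %||% 250L
  cand <- which(path$ok & ((path$n_zero == 0 & pre_onset) |
                             (path$n_zero > 0 &
                                path$D < path$threshold + margin)))
  # The baseline must be converged as deeply as the restricted refits it
  # is compared against, otherwise D is systematically deflated and the
  # scan over-shrinks. Re-polish the full model (an empty-mask refit,
  # cached and shared across penalty families) warm-started from the
  # best point seen in the loose phase.
  base_start <- fit0
  okrows <- which(path$ok & path$n_zero > 0)
  if (length(okrows)) {
    kbest <- okrows[which.min(path$chi2[okrows])]
    cand_fit <- path$refit[[kbest]]
    if (!is.null(cand_fit) && cand_fit$value < fit0$value)
      base_start <- cand_fit
  }
  deep_full <- refit_for_mask(character(0), base_start, problem,
                              confirm_maxit, "T:")
  chi2_0_tight <- min(fit0$value,
                      if (!is.null(deep_full)) deep_full$value else Inf)
  sel_k <- NA_integer_
  sel_fit <- NULL
  for (k in rev(cand)) {
    Z <- path$zero[[k]]
    if (length(Z) == 0) {
      sel_k <- k
      sel_fit <- fit0
      path$chi2[k] <- fit0$value
      path$D[k] <- max(fit0$value - chi2_0_tight, 0)
      path$refined[k] <- TRUE
      break
    }
    # two starts: the loose-phase refit, and the deep baseline's
    # optimum projected onto the mask — the latter anchors every
    # candidate to one basin so the D differences are consistent
    starts_k <- list(path$refit[[k]])
    if (!is.null(deep_full)) starts_k <- c(starts_k, list(deep_full))
    tf <- refit_for_mask(Z, starts_k, problem, confirm_maxit, "T:")
    if (is.null(tf)) next
    chi2_0_tight <- min(chi2_0_tight, tf$value)
    D_k <- max(tf$value - chi2_0_tight, 0)
    path$chi2[k] <- tf$value
    path$D[k] <- D_k
    path$admissible[k] <- D_k < path$threshold[k]
    path$refined[k] <- TRUE
    if (D_k < path$threshold[k]) {
      sel_k <- k
      sel_fit <- tf
      break
    }
  }
  out$chi2_0 <- chi2_0_tight
  out$path <- path
  if (is.na(sel_k)) {
    warning("no admissible penalty strength; returning the unpenalized model")
    out$lambda_star <- 0
    out$final_fit <- fit0
    out$positives <- setdiff(names(fit0$r),
                             zero_set(fit0$r, spec$epsilon))
    return(out)
  }
  out$lambda_star <- path$lambda[sel_k]
  out$final_fit <- sel_fit
  Zsel <- zero_set(sel_fit$r, spec$epsilon)
  out$positives <- setdiff(names(sel_fit$r), Zsel)
  out
}

#' Select the parsimonious model along a scan
#'
#' The parsimonious penalty strength is the largest grid `lambda` whose
#' shrinkage is still compatible with the data:
#' \eqn{\lambda^* = \max\{\lambda > 0 \mid Z(\lambda) = \emptyset \
#' \mathrm{or}\ D(\lambda) < q_\alpha^{\#Z(\lambda)}\}}. The final
#' estimates are that grid point's unpenalized refit, and the positive
#' classifications are the fold-changes not in \eqn{Z(\lambda^*)}.
#'
#' @param path an `fr_regpath`.
#' @param alpha significance level (defaults to the scan's).
#' @return list with `lambda_star`, `fit` (the step-2 refit), `zero`
#'   (names in the zero set) and `positives`.
#' @export
parsimonious_lambda <- function(path, alpha = NULL) {
  stopifnot(inherits(path, "fr_regpath"))
  alpha <- alpha %||% path$alpha
  p <- path$path
  thr <- ifelse(p$n_zero >= 1, stats::qchisq(alpha, df = pmax(p$n_zero, 1)), Inf)
  pre_onset <- !cumsum(ifelse(is.na(p$n_zero), 0, p$n_zero) > 0)
  adm <- p$ok & ((p$n_zero == 0 & pre_onset) | (p$n_zero > 0 & p$D < thr))
  if (!any(adm, na.rm = TRUE)) {
    warning("no admissible penalty strength; returning the unpenalized model")
    return(list(lambda_star = 0, fit = path$fit0,
                zero = zero_set(path$fit0$r, path$spec$epsilon),
                positives = setdiff(names(path$fit0$r),
                                    zero_set(path$fit0$r, path$spec$epsilon))))
  }
  k <- max(which(adm))
  fit <- p$refit[[k]]
  Z <- zero_set(fit$r, path$spec$epsilon)
  list(lambda_star = p$lambda[k], fit = fit, zero = Z,
       positives = setdiff(names(fit$r), Z))
}

#' @export
print.fr_regpath <- function(x, ...) {
  cat("<fr_regpath>", x$spec$family,
      "(d =", paste0(x$spec$deformation, "),"),
      length(x$lambda_grid), "penalty strengths\n")
  cat("  chi2(0) =", format(x$chi2_0, digits = 6),
      "| lambda* =", format(x$lambda_star, digits = 4),
      "| positives:", length(x$positives), "\n")
  invisible(x)
}

#' Per-lambda records of a regularization scan
#'
#' @param x an `fr_regpath`.
#' @param ... unused.
#' @return tibble with `lambda`, `n_zero`, `chi2`, `D`, `threshold`,
#'   `admissible`, `ok`.
#' @export
tidy.fr_regpath <- function(x, ...) {
  dplyr::select(x$path, "lambda", "n_zero", "chi2", "D", "threshold",
                "admissible", "ok")
}

#' One-line summary of a regularization scan
#'
#' @param x an `fr_regpath`.
#' @param ... unused.
#' @return one-row tibble with the selected penalty strength, zero-set
#'   size, baseline objective and selection level.
#' @export
glance.fr_regpath <- function(x, ...) {
  k <- match(x$lambda_star, x$path$lambda)
  tibble::tibble(family = x$spec$family, deformation = x$spec$deformation,
                 lambda_star = x$lambda_star,
                 n_zero = if (!is.na(k)) x$path$n_zero[k] else 0L,
                 n_positive = length(x$positives),
                 chi2_0 = x$chi2_0,
                 D_star = if (!is.na(k)) x$path$D[k] else 0,
                 alpha = x$alpha)
}

#' Plot a regularization scan
#'
#' Shows the likelihood-ratio statistic \eqn{D(\lambda)} against its
#' chi-square threshold and the zero-set size along the penalty-strength
#' grid; the selected parsimonious strength is marked.
#'
#' @param object an `fr_regpath`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fr_regpath <- function(object, ...) {
  p <- dplyr::filter(object$path, .data$ok)
  long <- dplyr::bind_rows(
    tibble::tibble(lambda = p$lambda, value = p$D, what = "D(lambda)"),
    tibble::tibble(lambda = p$lambda, value = p$threshold,
                   what = "LRT threshold"),
    tibble::tibble(lambda = p$lambda, value = as.numeric(p$n_zero),
                   what = "# zero fold-changes"))
  ggplot2::ggplot(long, ggplot2::aes(.data$lambda, .data$value,
                                     colour = .data$what)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$lambda_star, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "penalty strength lambda", y = NULL, colour = NULL)
}
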