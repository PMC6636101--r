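#' Specify a sparsity penalty on the log-fold-changes
#'
#' Four penalty families act on the log10 fold-change vector `r` (never
#' on the reference parameters), each reducing to the l1/Lasso penalty
#' at deformation 0:
#'
#' * `"l1"`: \eqn{\nu(r) = \sum_i |r_i|}.
#' * `"lq"`: \eqn{\nu(r) = \sum_i |r_i|^q} with exponent `q = 1 -
#'   deformation`, non-convex for `q < 1`. Its gradient diverges at 0, so
#'   entries with \eqn{|r_i| \le \epsilon} use the finite clamped value
#'   \eqn{q\,\epsilon^{q-1}\,sign(r_i)}.
#' * `"elastic_net"`: \eqn{\nu(r) = (1-\alpha)\sum_i |r_i| + \alpha\sum_i
#'   r_i^2} with elasticity `alpha = deformation`.
#' * `"adaptive_lasso"`: \eqn{\nu(r) = \sum_i |r_i|\,|\hat r^{ML}_i|^{-\gamma}}
#'   with adaptivity `gamma = deformation`; the weights come from an
#'   unpenalized fit, floored at \eqn{\epsilon^{-\gamma}} when the ML
#'   fold-change is itself within \eqn{\epsilon} of zero.
#'
#' All families are evaluated on `r - target`; the default target 0
#' encodes the sparse two-cell-type prior.
#'
#' @param family one of `"l1"`, `"lq"`, `"adaptive_lasso"`,
#'   `"elastic_net"`.
#' @param deformation the single extra degree of freedom `d` (`1 - q`,
#'   `gamma`, or `alpha`); must be 0 for `"l1"`.
#' @param epsilon cut-off below which a fold-change counts as zero
#'   (default `1e-10`).
#' @param target vector (or scalar) `r*` the penalty is centred on.
#' @param weights adaptive-lasso weights; usually filled in from the
#'   unpenalized fit by [adaptive_weights()] / [scan_lambda()].
#' @return an object of class `fr_penalty`.
#' @export
penalty_spec <- function(family = c("l1", "lq", "adaptive_lasso",
                                    "elastic_net"),
                         deformation = 0, epsilon = 1e-10, target = 0,
                         weights = NULL) {
  family <- match.arg(family)
  d <- deformation
  stopifnot(epsilon > 0)
  if (family == "l1" && d != 0)
    stop("the l1 penalty has no deformation parameter")
  if (family == "lq" && (1 - d <= 0 || 1 - d > 1))
    stop("lq exponent q = 1 - deformation must lie in (0, 1]")
  if (family == "adaptive_lasso" && d < 0)
    stop("adaptivity gamma must be >= 0")
  if (family == "elastic_net" && (d < 0 || d > 1))
    stop("elasticity alpha must lie in [0, 1]")
  structure(list(family = family, deformation = d,
                 q = if (family == "lq") 1 - d else NULL,
                 gamma = if (family == "adaptive_lasso") d else NULL,
                 alpha = if (family == "elastic_net") d else NULL,
                 epsilon = epsilon, target = target, weights = weights),
            class = "fr_penalty")
}

#' @export
print.fr_penalty <- function(x, ...) {
  cat("<fr_penalty>", x$family, "deformation =", x$deformation, "\n")
  invisible(x)
}

#' Adaptive-lasso weights from an unpenalized fit
#'
#' \eqn{w_i = max(|\hat r^{ML}_i|, \epsilon)^{-\gamma}}; the floor keeps
#' the weight finite when the maximum-likelihood fold-change is itself
#' effectively zero.
#'
#' @param r_ml named maximum-likelihood fold-change estimates.
#' @param gamma adaptivity.
#' @param epsilon floor for `|r_ml|`.
#' @return named weight vector.
#' @export
adaptive_weights <- function(r_ml, gamma, epsilon = 1e-10) {
  w <- pmax(abs(r_ml), epsilon)^(-gamma)
  names(w) <- names(r_ml)
  w
}

spec_weights <- function(spec, r) {
  if (spec$family != "adaptive_lasso") return(NULL)
  if (is.null(spec$weights))
    stop("adaptive lasso requires weights from an unpenalized fit ",
         "(see adaptive_weights())")
  if (!is.null(names(spec$weights)) && !is.null(names(r)))
    spec$weights[names(r)]
  else rep_len(spec$weights, length(r))
}

#' Evaluate a penalty
#'
#' @param spec an [penalty_spec()].
#' @param r fold-change vector.
#' @return scalar \eqn{\nu(r - r^*) \ge 0}, zero exactly at the target.
#' @export
penalty_value <- function(spec, r) {
  s <- abs(r - spec$target)
  switch(spec$family,
         l1 = sum(s),
         lq = sum(s^spec$q),
         elastic_net = (1 - spec$alpha) * sum(s) + spec$alpha * sum(s^2),
         adaptive_lasso = sum(s * spec_weights(spec, r)))
}

#' Penalty gradient with the lq cut-off
#'
#' Entrywise derivative of the penalty with respect to `r`. For the lq
#' family, entries within `epsilon` of the target use the clamped
#' gradient \eqn{q\,\epsilon^{q-1}\,sign(r_i)} so the value stays finite.
#' Entries exactly at the target have a set-valued subgradient
#' (`sign(0) = [-1, 1]`); the returned vector carries 0 there, with the
#' interval bound magnitude available through attribute `"at_target"`
#' and [subgradient_interval()].
#'
#' @param spec an [penalty_spec()].
#' @param r fold-change vector.
#' @return numeric gradient vector with logical attribute `"at_target"`.
#' @export
penalty_gradient <- function(spec, r) {
  s <- r - spec$target
  sg <- sign(s)
  a <- abs(s)
  g <- switch(spec$family,
    l1 = sg,
    lq = {
      mag <- spec$q * pmax(a, spec$epsilon)^(spec$q - 1)
      sg * mag
    },
    elastic_net = (1 - spec$alpha) * sg + 2 * spec$alpha * s,
    adaptive_lasso = sg * spec_weights(spec, r))
  attr(g, "at_target") <- a == 0
  g
}

# Derivative of the penalty with respect to the split magnitude m >= 0
# (one-sided gradient); used by the penalized optimizer.
penalty_dmag <- function(spec, m, weights = NULL) {
  switch(spec$family,
         l1 = rep(1, length(m)),
         lq = spec$q * pmax(m, spec$epsilon)^(spec$q - 1),
         elastic_net = (1 - spec$alpha) + 2 * spec$alpha * m,
         adaptive_lasso = if (is.null(weights)) spec$weights else weights)
}

#' Subgradient interval of the penalty term at a zero fold-change
#'
#' For a fold-change at the target (within `epsilon` for lq, where the
#' clamped penalty is effectively the modulus and hence convex), the set
#' \eqn{\lambda \nabla\nu(\hat r)_i} is the symmetric interval returned
#' here. A fit is optimal in that coordinate when the likelihood gradient
#' lies inside it.
#'
#' @param spec an [penalty_spec()].
#' @param lambda penalty strength.
#' @param r fold-change vector (to check the precondition and pick the
#'   adaptive weight).
#' @param i coordinate index.
#' @return numeric `c(low, high)`.
#' @export
subgradient_interval <- function(spec, lambda, r, i) {
  s <- abs(r[i] - spec$target)
  tol <- if (spec$family == "lq") spec$epsilon else 0
  if (s > tol)
    stop("subgradient interval is only defined at a zero fold-change")
  bound <- switch(spec$family,
                  l1 = 1,
                  lq = spec$q * spec$epsilon^(spec$q - 1),
                  elastic_net = 1 - spec$alpha,
                  adaptive_lasso = spec_weights(spec, r)[i])
  lambda * bound * c(-1, 1)
}

#' Check first-order optimality of a penalized fit
#'
#' Verifies, parameter by parameter, the stationarity conditions of the
#' penalized objective \eqn{\chi^2_{ML} + \lambda\nu(r)}: the likelihood
#' gradient must vanish for all reference parameters and for every
#' nonzero fold-change, while at a zero fold-change the likelihood
#' gradient must lie inside the penalty's subgradient interval (the
#' penalty term then dominates the likelihood contribution).
#'
#' @param problem an `fr_problem`.
#' @param fit an `fr_fit`.
#' @param spec an [penalty_spec()].
#' @param lambda penalty strength the fit was computed at.
#' @param tol gradient tolerance on the chi-square scale (default 1e-3).
#' @return tibble with one row per parameter: `parameter`, `block`,
#'   `estimate`, `gradient`, `criterion`, `satisfied`, `margin`.
#' @export
check_optimality <- function(problem, fit, spec, lambda, tol = 1e-3) {
  cc <- chi2_ml(problem, fit$log_p0, fit$r, gradient = TRUE)
  s <- abs(fit$r - spec$target)
  zero_tol <- if (spec$family == "lq") spec$epsilon else 0
  rows_p <- tibble::tibble(
    parameter = names(fit$log_p0), block = "reference",
    estimate = unname(fit$log_p0), gradient = unname(cc$grad_p0),
    criterion = "interior",
    satisfied = abs(unname(cc$grad_p0)) < tol,
    margin = tol - abs(unname(cc$grad_p0)))
  at_zero <- s <= zero_tol
  pen_g <- penalty_gradient(spec, fit$r)
  crit <- ifelse(at_zero, "subgradient", "interior")
  gr_r <- unname(cc$grad_r)
  total <- gr_r + lambda * ifelse(at_zero, 0, unname(pen_g))
  hi <- vapply(seq_along(fit$r), function(i) {
    if (at_zero[i]) subgradient_interval(spec, lambda, fit$r, i)[2] else NA_real_
  }, numeric(1))
  satisfied <- ifelse(at_zero, abs(gr_r) <= hi + tol, abs(total) < tol)
  margin <- ifelse(at_zero, hi + tol - abs(gr_r), tol - abs(total))
  rows_r <- tibble::tibble(
    parameter = names(fit$r), block = "fold_change",
    estimate = unname(fit$r), gradient = gr_r,
    criterion = crit, satisfied = satisfied, margin = margin)
  dplyr::bind_rows(rows_p, rows_r)
}
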