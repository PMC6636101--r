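# Small analytic models and problems reused across the suite.

# one-state exponential decay dx/dt = -k x, x(0) = 1
decay_model <- function() {
  ode_model(state_names = "x",
            param_names = "k",
            rhs = function(t, x, p) -p[["k"]] * x,
            x0 = 1)
}

# two-state linear cascade dx1 = -k1 x1, dx2 = k1 x1 - k2 x2, x(0) = (1, 0)
cascade_model <- function() {
  ode_model(state_names = c("x1", "x2"),
            param_names = c("k1", "k2"),
            rhs = function(t, x, p) {
              c(-p[["k1"]] * x[1],
                p[["k1"]] * x[1] - p[["k2"]] * x[2])
            },
            x0 = c(1, 0))
}

# n constant states x_i(t) = p_i observed on the log10 scale: the
# objective is exactly quadratic in the log10 parameters and
# fold-changes, which makes closed-form oracles available
const_model <- function(n = 2) {
  pn <- paste0("p", seq_len(n))
  ode_model(state_names = paste0("x", seq_len(n)),
            param_names = pn,
            rhs = function(t, x, p) rep(0, length(x)),
            x0 = function(p) unname(p[pn]),
            observables = tibble::tibble(name = paste0("y", seq_len(n)),
                                         state = paste0("x", seq_len(n)),
                                         transform = "log10"),
            param_roles = stats::setNames(rep("p0", n), pn))
}

# Gaussian two-cell-type problem on the const model: y_i measured once
# per cell type; b gives the true log10 fold-changes, sigma the noise sd
# recorded with the (noise-free) data. chi2 is quadratic with
# per-coordinate curvature 1/(2 sigma^2) after profiling out the
# reference parameters.
const_problem <- function(b, sigma = 0.1, base = 0) {
  n <- length(b)
  model <- const_model(n)
  conds <- list(base = condition("base"))
  meas <- dplyr::bind_rows(
    tibble::tibble(observableId = paste0("y", seq_len(n)),
                   conditionId = "base", cellType = 0L, time = 0,
                   measurement = base, sd = sigma),
    tibble::tibble(observableId = paste0("y", seq_len(n)),
                   conditionId = "base", cellType = 1L, time = 0,
                   measurement = base + b, sd = sigma))
  fc_problem(model, meas, conds, penalized = model$param_names,
             control = list(n_starts = 2L))
}

# two-parameter decay problem (decay rate + initial value), data
# simulated noise-free from known parameters for both cell types
decay2_model <- function() {
  ode_model(state_names = "x",
            param_names = c("k", "a"),
            rhs = function(t, x, p) -p[["k"]] * x,
            x0 = function(p) unname(p[["a"]]),
            param_roles = c(k = "px", a = "p0"))
}

decay2_problem <- function(r_true = c(k = 0.5, a = 0), sigma = 0.05,
                           times = seq(0, 4, length.out = 9)) {
  model <- decay2_model()
  truth0 <- c(k = 0, a = 0)    # log10: k = 1, a = 1
  conds <- list(base = condition("base"))
  rows <- list()
  for (ct in 0:1) {
    lp <- map_celltype_params(truth0, r_true, ct)
    tr <- simulate_model(model, lp, times)
    rows[[ct + 1]] <- tibble::tibble(observableId = "x",
                                     conditionId = "base",
                                     cellType = ct, time = times,
                                     measurement = tr$states[, "x"],
                                     sd = sigma)
  }
  fc_problem(model, dplyr::bind_rows(rows), conds,
             penalized = model$param_names,
             control = list(n_starts = 2L))
}

# hand-written R version of the gene-network right-hand side, used as an
# oracle against the compiled rate function
hillnet_rhs_oracle <- function(model, log_params, x) {
  p <- 10^log_params[model$param_names]
  genes <- model$genes
  n <- length(genes)
  topo <- model$topology
  m <- x[seq_len(n)]
  prot <- x[n + seq_len(n)]
  deg <- p[["deg"]]
  dm <- numeric(n); dp <- numeric(n)
  for (i in seq_len(n)) {
    g <- genes[i]
    H <- 1
    for (e in which(topo$target == g)) {
      a <- max(prot[match(topo$regulator[e], genes)], 0)
      K <- p[[paste0("km_", topo$edge[e])]]
      nh <- p[[paste0("hill_", topo$edge[e])]]
      act <- (a / K)^nh / (1 + (a / K)^nh)
      H <- H * if (topo$sign[e] > 0) act else 1 - act
    }
    dm[i] <- model$tmul[i] * p[[paste0("pro_", g)]] * H -
      deg * model$dmul[i] * m[i]
    dp[i] <- model$lmul[i] * p[[paste0("rbs_", g)]] * m[i] - deg * prot[i]
  }
  c(dm, dp)
}
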