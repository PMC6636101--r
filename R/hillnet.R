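#' Built-in 6-gene regulatory topology
#'
#' A synthetic six-gene, eight-edge regulatory topology in the style of
#' published gene-network benchmark challenges. Each gene contributes an
#' mRNA and a protein state; transcription of a regulated gene follows
#' Hill kinetics in its regulator proteins, translation is proportional
#' to mRNA times the ribosomal strength, and decay of every species uses
#' one shared degradation rate. Gene 1 is repressed by protein 6, closing
#' a negative feedback loop through the activation cascade.
#'
#' @param n_genes 6 for the full network or 3 for the reduced cascade
#'   used in fast end-to-end tests (genes 1-3 with their two edges plus a
#'   3->1 feedback repression).
#' @return tibble with columns `edge`, `regulator`, `target`, `sign`.
#' @export
hill_network_topology <- function(n_genes = 6) {
  if (n_genes == 6) {
    tibble::tibble(
      edge = paste0("e", 1:8),
      regulator = c("g1", "g1", "g2", "g3", "g4", "g4", "g5", "g6"),
      target    = c("g2", "g3", "g4", "g4", "g5", "g2", "g6", "g1"),
      sign      = c(1L, 1L, 1L, -1L, 1L, -1L, 1L, -1L))
  } else if (n_genes == 3) {
    tibble::tibble(
      edge = paste0("e", 1:3),
      regulator = c("g1", "g2", "g3"),
      target    = c("g2", "g3", "g1"),
      sign      = c(1L, 1L, -1L))
  } else {
    stop("only the 6-gene and 3-gene topologies are built in")
  }
}

# Fixed synthetic reference parameter values for the built-in networks.
# Strengths and half-saturation constants were drawn once log-uniformly
# from [0.1, 10] and Hill exponents uniformly from {1, 2, 3, 4} under a
# fixed seed; the shared degradation rate is 1 inverse time unit for the
# reference cell type. The values are frozen here so the reference
# network is a fixed object, like a challenge gold standard would be.
hill_network_reference_values <- function(n_genes = 6) {
  if (n_genes == 6) {
    list(pro = c(6.7548, 7.4843, 0.3735, 4.5803, 1.9208, 1.0919),
         rbs = c(2.9729, 0.1859, 2.0606, 2.5712, 0.8232, 2.7430),
         deg = 1,
         km = c(7.4019, 0.3242, 0.8406, 7.5863, 9.0459, 0.1718, 0.8912, 1.3203),
         hill = c(3, 3, 1, 1, 3, 4, 1, 3))
  } else {
    list(pro = c(6.7548, 7.4843, 0.3735),
         rbs = c(2.9729, 0.1859, 2.0606),
         deg = 1,
         km = c(0.3242, 0.8406, 1.3203),
         hill = c(2, 1, 3))
  }
}

#' Build the Hill-kinetics gene-network model
#'
#' Constructs the two-state-per-gene ODE model (mRNA and protein for each
#' gene) with Hill-kinetics transcription on every regulatory edge. For
#' the 6-gene topology the kinetic parameter census is 6 transcription
#' strengths + 6 ribosomal strengths + 1 shared degradation rate +
#' 8 half-saturation constants + 8 Hill exponents = 29.
#'
#' Simulation and exact forward sensitivities run through a compiled
#' adaptive Dormand-Prince 5(4) integrator.
#'
#' @param topology edge table as returned by [hill_network_topology()].
#' @param reference optional list of reference parameter values
#'   (`pro`, `rbs`, `deg`, `km`, `hill`); defaults to the frozen
#'   synthetic reference set.
#' @param control integrator settings (`rtol`, `atol`, `max_steps`).
#' @return an `fr_model` with backend `"hillnet"`. The reference
#'   parameter values (log10) are attached as attribute
#'   `"reference_log10"`.
#' @export
hill_network_model <- function(topology = hill_network_topology(),
                               reference = NULL,
                               control = list()) {
  genes <- sort(unique(c(topology$regulator, topology$target)))
  n <- length(genes)
  ne <- nrow(topology)
  if (!all(topology$sign %in% c(-1L, 1L)))
    stop("edge signs must be +1 (activation) or -1 (repression)")
  if (n == 6 && ne != 8)
    stop("the 6-gene network needs exactly 8 regulated edges ",
         "(29-parameter structure)")
  if (is.null(reference)) reference <- hill_network_reference_values(n)
  param_names <- c(paste0("pro_", genes), paste0("rbs_", genes), "deg",
                   paste0("km_", topology$edge),
                   paste0("hill_", topology$edge))
  ref <- c(reference$pro, reference$rbs, reference$deg,
           reference$km, reference$hill)
  names(ref) <- param_names
  state_names <- c(paste0("mrna_", genes), paste0("protein_", genes))
  # strengths and Km are generated log-uniformly in [0.1, 10] and
  # fold-changes span at most one decade, so [-2, 2] (log10) brackets
  # every admissible value with a decade of margin; Hill exponents stay
  # in [1, 4] by model construction
  bounds <- tibble::tibble(
    name = param_names,
    lower = ifelse(startsWith(param_names, "hill_"), 0, -2),
    upper = ifelse(startsWith(param_names, "hill_"), log10(4), 2))
  ctrl <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10,
                                 max_steps = 100000L,
                                 sens_err_states = FALSE), control)
  m <- structure(list(
    backend = "hillnet",
    state_names = state_names,
    param_names = param_names,
    param_roles = stats::setNames(rep("px", length(param_names)), param_names),
    genes = genes,
    net = list(n = n,
               reg = match(topology$regulator, genes),
               tgt = match(topology$target, genes),
               sgn = as.integer(topology$sign)),
    topology = topology,
    x0 = function(p) rep(0, 2 * n),
    observables = tibble::tibble(name = state_names, state = state_names,
                                 transform = "identity"),
    tmul = rep(1, n), lmul = rep(1, n), dmul = rep(1, n),
    bounds = bounds,
    control = ctrl), class = "fr_model")
  attr(m, "reference_log10") <- log10(ref)
  m
}

simulate_hillnet <- function(model, log_params, times, sens) {
  p <- 10^unname(log_params[model$param_names])
  t_in <- as.numeric(times)
  prepend <- t_in[1] > 0
  if (prepend) t_in <- c(0, t_in)
  out <- hillnet_sim_cpp(model$net, p, model$tmul, model$lmul, model$dmul,
                         model$x0(p), t_in, sens,
                         model$control$rtol, model$control$atol,
                         as.integer(model$control$max_steps),
                         isTRUE(model$control$sens_err_states))
  if (prepend && isTRUE(out$ok)) {
    out$states <- out$states[-1L, , drop = FALSE]
    if (sens) out$sens <- out$sens[-1L, , drop = FALSE]
  }
  if (!isTRUE(out$ok)) {
    return(structure(list(times = times, states = NULL, sens = NULL,
                          ok = FALSE), class = "fr_trajectory"))
  }
  states <- out$states
  colnames(states) <- model$state_names
  S <- NULL
  if (sens) {
    S <- array(out$sens, dim = c(length(times), length(model$state_names),
                                 length(model$param_names)),
               dimnames = list(NULL, model$state_names, model$param_names))
  }
  structure(list(times = times, states = states, sens = S, ok = TRUE),
            class = "fr_trajectory")
}

# Right-hand side of the network ODE at one state (used for tests and
# diagnostics; simulation itself runs in compiled code).
hillnet_rhs <- function(model, log_params, x) {
  p <- 10^unname(log_params[model$param_names])
  hillnet_derivs_cpp(model$net, p, model$tmul, model$lmul, model$dmul, x)
}
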