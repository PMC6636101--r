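#' Declare an ODE model
#'
#' An `fr_model` bundles the pieces needed to simulate one biochemical
#' system shared by two cell types: state names, a rate function
#' \eqn{f(t, x, p)}, initial conditions, an observation map and log10
#' bounds for every parameter. All parameters are strictly positive;
#' estimation happens on the log10 scale throughout the package.
#'
#' The rate function receives the time, the current state vector and the
#' *natural-scale* named parameter vector, and must return the vector of
#' time derivatives (one entry per state). External inputs `u(t, p_u)` are
#' expressed inside `rhs` using parameters with role `"pu"`.
#'
#' @param state_names character vector of state identifiers.
#' @param param_names character vector of parameter identifiers.
#' @param rhs function `(t, x, p) -> dx/dt`, with `p` the named
#'   natural-scale parameter vector.
#' @param x0 either a numeric vector of initial values (one per state) or
#'   a function `p -> x(0)` so that initial conditions can be parameters
#'   (role `"p0"`).
#' @param observables tibble with columns `name`, `state`, `transform`
#'   (`"identity"` or `"log10"`); defaults to observing every state
#'   directly.
#' @param param_roles named character vector assigning each parameter one
#'   of the roles `"p0"` (initial condition), `"px"` (kinetic), `"pu"`
#'   (input), `"py"` (observation); defaults to `"px"` for all.
#' @param bounds tibble with columns `name`, `lower`, `upper` giving
#'   log10 box constraints; defaults to \[-5, 3\] for every parameter.
#' @param control list of integrator settings (`rtol`, `atol`,
#'   `max_steps`).
#'
#' @return an object of class `fr_model`.
#' @export
ode_model <- function(state_names, param_names, rhs, x0,
                      observables = NULL, param_roles = NULL,
                      bounds = NULL, control = list()) {
  stopifnot(is.character(state_names), is.character(param_names),
            is.function(rhs))
  if (is.numeric(x0)) {
    if (length(x0) != length(state_names))
      stop("x0 must have one entry per state")
    x0_num <- x0
    x0 <- function(p) x0_num
  }
  stopifnot(is.function(x0))
  if (is.null(observables)) {
    observables <- tibble::tibble(name = state_names, state = state_names,
                                  transform = "identity")
  }
  check_observables(observables, state_names)
  if (is.null(param_roles)) {
    param_roles <- stats::setNames(rep("px", length(param_names)), param_names)
  }
  stopifnot(all(names(param_roles) %in% param_names),
            all(param_roles %in% c("p0", "px", "pu", "py")))
  if (is.null(bounds)) {
    bounds <- tibble::tibble(name = param_names, lower = -5, upper = 3)
  }
  stopifnot(all(param_names %in% bounds$name))
  ctrl <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10, max_steps = 100000L),
                            control)
  structure(list(backend = "r", state_names = state_names,
                 param_names = param_names, rhs = rhs, x0 = x0,
                 observables = observables, param_roles = param_roles,
                 bounds = bounds, control = ctrl),
            class = "fr_model")
}

check_observables <- function(obs, state_names) {
  stopifnot(is.data.frame(obs),
            all(c("name", "state", "transform") %in% names(obs)))
  bad <- setdiff(obs$state, state_names)
  if (length(bad))
    stop("observable references unknown state(s): ", paste(bad, collapse = ", "))
  stopifnot(all(obs$transform %in% c("identity", "log10")))
  invisible(obs)
}

#' @export
print.fr_model <- function(x, ...) {
  cat("<fr_model> backend:", x$backend, "\n")
  cat("  states (", length(x$state_names), "): ",
      paste(utils::head(x$state_names, 8), collapse = ", "),
      if (length(x$state_names) > 8) ", ..." else "", "\n", sep = "")
  cat("  parameters:", length(x$param_names), "\n")
  cat("  observables:", nrow(x$observables), "\n")
  invisible(x)
}

#' Define an experimental condition
#'
#' A condition pairs a cell-type label with an optional kinetic
#' perturbation of the model (gene knockout, five-fold accelerated mRNA
#' degradation, or doubled mRNA synthesis).
#'
#' @param id condition identifier (character).
#' @param cell_type 0 (reference) or 1.
#' @param perturbation `NULL` or the result of [perturbation()].
#' @return a list of class `fr_condition`.
#' @export
condition <- function(id, cell_type = 0L, perturbation = NULL) {
  stopifnot(cell_type %in% c(0L, 1L))
  if (is.null(perturbation)) perturbation <- perturbation("none")
  structure(list(id = as.character(id), cell_type = as.integer(cell_type),
                 perturbation = perturbation),
            class = "fr_condition")
}

#' Declare a kinetic perturbation
#'
#' @param kind one of `"none"`, `"knockout"`, `"degradation_x5"`,
#'   `"synthesis_x2"`.
#' @param gene gene identifier the perturbation applies to (ignored for
#'   `"none"`).
#' @return a list of class `fr_perturbation`.
#' @export
perturbation <- function(kind = c("none", "knockout", "degradation_x5",
                                  "synthesis_x2"),
                         gene = NULL) {
  kind <- match.arg(kind)
  if (kind != "none" && is.null(gene))
    stop("perturbation '", kind, "' needs a gene")
  structure(list(kind = kind, gene = gene), class = "fr_perturbation")
}

#' Apply a perturbation to a model
#'
#' Returns a modified copy of the model; the input is untouched. Knockout
#' zeroes both synthesis rates of the gene (it is not produced at all),
#' `degradation_x5` multiplies that gene's mRNA decay term by five, and
#' `synthesis_x2` doubles its transcription rate. State dimensions are
#' never changed.
#'
#' @param model an `fr_model` (gene-network backend for non-trivial
#'   perturbations).
#' @param pert an [perturbation()] object.
#' @return the perturbed `fr_model`.
#' @export
apply_perturbation <- function(model, pert) {
  stopifnot(inherits(model, "fr_model"), inherits(pert, "fr_perturbation"))
  if (pert$kind == "none") return(model)
  if (model$backend != "hillnet")
    stop("gene perturbations require a gene-network model")
  g <- match(pert$gene, model$genes)
  if (is.na(g)) stop("unknown gene: ", pert$gene)
  switch(pert$kind,
         knockout = {
           model$tmul[g] <- 0
           model$lmul[g] <- 0
         },
         degradation_x5 = {
           model$dmul[g] <- model$dmul[g] * 5
         },
         synthesis_x2 = {
           model$tmul[g] <- model$tmul[g] * 2
         })
  model
}

#' Simulate a model
#'
#' Numerically integrates the ODE system from `x(0)` over the requested
#' time grid, optionally propagating forward sensitivities of the states
#' with respect to the log10 parameters. Any perturbation attached to
#' `condition` is applied before integration. Integration failures are
#' reported through `ok = FALSE` in the returned trajectory (callers map
#' this to an infinite objective) rather than as an error.
#'
#' For general models sensitivities are computed by central finite
#' differences on the log10 parameters (step `1e-4`); the compiled
#' gene-network backend uses exact forward sensitivity equations.
#'
#' @param model an `fr_model`.
#' @param log_params named numeric vector, log10 of every model parameter.
#' @param times ascending numeric vector starting at 0.
#' @param condition optional [condition()]; its perturbation is applied.
#' @param sens logical, also return sensitivities `dx/dlog10 p`.
#' @return an `fr_trajectory`: list with `times`, `states` (time by
#'   state matrix), `sens` (time x state x parameter array or `NULL`) and
#'   `ok`.
#' @export
simulate_model <- function(model, log_params, times, condition = NULL,
                           sens = FALSE) {
  stopifnot(inherits(model, "fr_model"))
  if (is.unsorted(times, strictly = FALSE) || times[1] < 0)
    stop("times must be ascending and start at or after 0")
  miss <- setdiff(model$param_names, names(log_params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  if (!is.null(condition) && inherits(condition, "fr_condition"))
    model <- apply_perturbation(model, condition$perturbation)
  if (model$backend == "hillnet") {
    simulate_hillnet(model, log_params, times, sens)
  } else {
    simulate_r(model, log_params, times, sens)
  }
}

simulate_r <- function(model, log_params, times, sens) {
  p <- 10^log_params[model$param_names]
  names(p) <- model$param_names
  run <- function(p) {
    y0 <- model$x0(p)
    names(y0) <- model$state_names
    t_in <- times
    prepend <- t_in[1] > 0
    if (prepend) t_in <- c(0, t_in)
    if (length(t_in) == 1) {            # only t = 0 requested
      m <- matrix(y0, nrow = 1, dimnames = list(NULL, model$state_names))
      return(m)
    }
    out <- try(deSolve::lsoda(y0, t_in, function(t, x, parms) {
      list(model$rhs(t, x, parms))
    }, p, rtol = model$control$rtol, atol = model$control$atol), silent = TRUE)
    if (inherits(out, "try-error") || any(!is.finite(out)) ||
        nrow(out) < length(t_in)) return(NULL)
    m <- out[if (prepend) -1L else TRUE, -1L, drop = FALSE]
    colnames(m) <- model$state_names
    m
  }
  states <- run(p)
  if (is.null(states)) {
    return(structure(list(times = times, states = NULL, sens = NULL,
                          ok = FALSE), class = "fr_trajectory"))
  }
  S <- NULL
  if (sens) {
    h <- 1e-4
    S <- array(0, dim = c(length(times), length(model$state_names),
                          length(model$param_names)),
               dimnames = list(NULL, model$state_names, model$param_names))
    for (k in seq_along(model$param_names)) {
      lp_hi <- log_params; lp_hi[model$param_names[k]] <- lp_hi[model$param_names[k]] + h
      lp_lo <- log_params; lp_lo[model$param_names[k]] <- lp_lo[model$param_names[k]] - h
      hi <- run(10^lp_hi[model$param_names])
      lo <- run(10^lp_lo[model$param_names])
      if (is.null(hi) || is.null(lo)) {
        return(structure(list(times = times, states = states, sens = NULL,
                              ok = FALSE), class = "fr_trajectory"))
      }
      S[, , k] <- (hi - lo) / (2 * h)
    }
  }
  structure(list(times = times, states = states, sens = S, ok = TRUE),
            class = "fr_trajectory")
}

#' @export
print.fr_trajectory <- function(x, ...) {
  cat("<fr_trajectory>", length(x$times), "time points,",
      if (x$ok) "ok" else "FAILED", "\n")
  invisible(x)
}

#' Tidy a simulated trajectory into a long tibble
#'
#' @param x an `fr_trajectory`.
#' @param ... unused.
#' @return tibble with columns `time`, `state`, `value`.
#' @export
tidy.fr_trajectory <- function(x, ...) {
  if (!x$ok) return(tibble::tibble(time = numeric(), state = character(),
                                   value = numeric()))
  tibble::as_tibble(as.data.frame(x$states)) |>
    dplyr::mutate(time = x$times) |>
    tidyr::pivot_longer(-"time", names_to = "state", values_to = "value")
}
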