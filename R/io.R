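#' Read a measurement table
#'
#' Strictly parses the tab-separated measurement format: columns
#' `observableId`, `conditionId`, `cellType`, `time`, `measurement`,
#' `sd`.
#'
#' @param path TSV file.
#' @return measurement tibble.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  d <- readr::read_tsv(path, col_types = readr::cols(
    observableId = readr::col_character(),
    conditionId = readr::col_character(),
    cellType = readr::col_integer(),
    time = readr::col_double(),
    measurement = readr::col_double(),
    sd = readr::col_double()))
  miss <- setdiff(measurement_cols, names(d))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  d
}

#' Write a measurement table
#'
#' @param measurements measurement tibble.
#' @param path output TSV file.
#' @return the path, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_tsv(measurements[measurement_cols], path)
  invisible(path)
}

model_from_config <- function(cfg) {
  type <- cfg$type %||% "ode"
  if (type == "hill_network") {
    topo <- dplyr::bind_rows(lapply(cfg$topology$edges, tibble::as_tibble))
    return(hill_network_model(topo, reference = cfg$reference,
                              control = cfg$control %||% list()))
  }
  states <- as.character(cfg$states)
  pars <- dplyr::bind_rows(lapply(cfg$parameters, tibble::as_tibble))
  if (!all(c("name") %in% names(pars)))
    stop("model.parameters entries need at least a 'name' field")
  if (is.null(pars$role)) pars$role <- "px"
  if (is.null(pars$lower)) pars$lower <- -5
  if (is.null(pars$upper)) pars$upper <- 3
  exprs <- lapply(states, function(s) {
    e <- cfg$rates[[s]]
    if (is.null(e)) stop("no rate expression for state '", s, "'")
    parse(text = e)[[1]]
  })
  names(exprs) <- states
  rhs <- function(t, x, p) {
    env <- list2env(as.list(c(x, p)))
    env$t <- t
    vapply(exprs, eval, numeric(1), envir = env)
  }
  x0cfg <- cfg$x0
  x0 <- function(p) {
    vapply(states, function(s) {
      v <- x0cfg[[s]]
      if (is.null(v)) 0
      else if (is.character(v)) unname(p[[v]])
      else as.numeric(v)
    }, numeric(1))
  }
  obs <- if (is.null(cfg$observables)) NULL else
    dplyr::bind_rows(lapply(cfg$observables, function(o) {
      tibble::tibble(name = o$name, state = o$state,
                     transform = o$transform %||% "identity")
    }))
  m <- ode_model(states, pars$name, rhs, x0, observables = obs,
                 param_roles = stats::setNames(pars$role, pars$name),
                 bounds = tibble::tibble(name = pars$name,
                                         lower = pars$lower,
                                         upper = pars$upper))
  m$rate_strings <- lapply(cfg$rates, identity)
  m$x0_config <- x0cfg
  m$config <- cfg
  m
}

conditions_from_config <- function(cfg) {
  if (is.null(cfg)) return(list(base = condition("base")))
  conds <- lapply(cfg, function(cc) {
    pert <- if (is.null(cc$perturbation)) NULL else
      perturbation(cc$perturbation$kind, gene = cc$perturbation$gene)
    condition(cc$id, cell_type = cc$cell_type %||% 0L, perturbation = pert)
  })
  names(conds) <- vapply(conds, `[[`, "", "id")
  conds
}

#' Load a problem bundle from YAML
#'
#' Reads a declarative problem file (model, conditions, penalized
#' parameter declaration, penalty and scan configuration, seed) and its
#' measurement TSV, validates every cross-reference eagerly, and
#' assembles the estimation problem.
#'
#' @param path YAML problem file; the measurement file path inside it is
#'   resolved relative to this file.
#' @return an `fr_bundle`: list with `problem` (`fr_problem`), `penalty`
#'   (`fr_penalty` or `NULL`), `scan` (grid configuration), `seed`.
#' @export
load_problem <- function(path) {
  if (!file.exists(path)) stop("problem file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (fld in c("model", "measurements"))
    if (is.null(cfg[[fld]]))
      stop(path, ": missing top-level field '", fld, "'")
  model <- model_from_config(cfg$model)
  mfile <- cfg$measurements
  if (!file.exists(mfile))
    mfile <- file.path(dirname(path), cfg$measurements)
  measurements <- read_measurements(mfile)
  conds <- conditions_from_config(cfg$conditions)
  fold_bounds <- if (!is.null(cfg$fold_bounds))
    dplyr::bind_rows(lapply(cfg$fold_bounds, tibble::as_tibble)) else NULL
  problem <- fc_problem(model, measurements, conds,
                        penalized = as.character(cfg$penalized %||%
                                                   model$param_names),
                        fixed_zero = as.character(cfg$fixed_zero %||%
                                                    character()),
                        fold_bounds = fold_bounds,
                        control = cfg$control %||% list())
  pen <- if (!is.null(cfg$penalty)) {
    penalty_spec(cfg$penalty$family,
                 deformation = cfg$penalty$deformation %||% 0,
                 epsilon = cfg$penalty$epsilon %||% 1e-10,
                 target = cfg$penalty$target %||% 0)
  }
  scan <- utils::modifyList(list(lambda_min = 1e-4, lambda_max = 1e6,
                                 n_lambda = 41L, alpha = 0.95),
                            cfg$scan %||% list())
  structure(list(problem = problem, penalty = pen, scan = scan,
                 seed = cfg$seed %||% 1L, source = path),
            class = "fr_bundle")
}

#' Save a problem bundle to YAML + TSV
#'
#' Only declaratively defined models (built from YAML rate strings or
#' gene-network topologies) can be serialized.
#'
#' @param bundle an `fr_bundle` (or plain `fr_problem`).
#' @param dir output directory; writes `problem.yaml` and
#'   `measurements.tsv`.
#' @return path of the written YAML, invisibly.
#' @export
save_problem <- function(bundle, dir) {
  if (inherits(bundle, "fr_problem"))
    bundle <- list(problem = bundle, penalty = NULL, scan = NULL, seed = 1L)
  problem <- bundle$problem
  model <- problem$model
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mcfg <- if (model$backend == "hillnet") {
    list(type = "hill_network",
         topology = list(edges = lapply(seq_len(nrow(model$topology)),
                                        function(k) as.list(model$topology[k, ]))))
  } else if (!is.null(model$rate_strings)) {
    list(type = "ode", states = model$state_names,
         parameters = lapply(seq_along(model$param_names), function(k) {
           nm <- model$param_names[k]
           b <- model$bounds[model$bounds$name == nm, ]
           list(name = nm, role = unname(model$param_roles[[nm]]),
                lower = b$lower, upper = b$upper)
         }),
         rates = model$rate_strings,
         x0 = model$x0_config,
         observables = lapply(seq_len(nrow(model$observables)), function(k)
           as.list(model$observables[k, ])))
  } else {
    stop("only declaratively defined models can be serialized")
  }
  cfg <- list(model = mcfg,
              measurements = "measurements.tsv",
              conditions = lapply(problem$conditions, function(cc) {
                out <- list(id = cc$id)
                if (cc$perturbation$kind != "none")
                  out$perturbation <- list(kind = cc$perturbation$kind,
                                           gene = cc$perturbation$gene)
                out
              }),
              penalized = problem$penalized,
              fixed_zero = problem$fixed_zero,
              seed = bundle$seed %||% 1L)
  names(cfg$conditions) <- NULL
  if (!is.null(bundle$penalty))
    cfg$penalty <- list(family = bundle$penalty$family,
                        deformation = bundle$penalty$deformation,
                        epsilon = bundle$penalty$epsilon,
                        target = bundle$penalty$target)
  if (!is.null(bundle$scan)) cfg$scan <- bundle$scan
  write_measurements(problem$measurements, file.path(dir, "measurements.tsv"))
  out <- file.path(dir, "problem.yaml")
  yaml::write_yaml(cfg, out)
  invisible(out)
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 17,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a fit result to JSON
#'
#' Numbers carry 17 significant digits so refit-equality checks survive
#' the round trip.
#'
#' @param fit an `fr_fit`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  json_write(list(chi2 = fit$value,
                  convergence = fit$convergence,
                  iterations = fit$iterations,
                  n_starts = fit$n_starts,
                  mask = as.list(fit$mask),
                  log_p0 = as.list(fit$log_p0),
                  r = as.list(fit$r)), path)
}

#' Write the per-lambda scan summary
#'
#' @param path_obj an `fr_regpath`.
#' @param tsv,json optional output files for the TSV summary and the
#'   full per-lambda JSON records.
#' @return invisibly, the tidied path.
#' @export
write_regpath <- function(path_obj, tsv = NULL, json = NULL) {
  tbl <- tidy.fr_regpath(path_obj)
  if (!is.null(tsv)) readr::write_tsv(tbl, tsv)
  if (!is.null(json)) {
    recs <- lapply(seq_len(nrow(path_obj$path)), function(k) {
      row <- path_obj$path[k, ]
      list(lambda = row$lambda, ok = row$ok, n_zero = row$n_zero,
           zero = as.list(row$zero[[1]]), chi2 = row$chi2, D = row$D,
           threshold = row$threshold, admissible = row$admissible,
           r = if (!is.null(row$refit[[1]])) as.list(row$refit[[1]]$r))
    })
    json_write(list(chi2_0 = path_obj$chi2_0,
                    lambda_star = path_obj$lambda_star,
                    alpha = path_obj$alpha,
                    family = path_obj$spec$family,
                    deformation = path_obj$spec$deformation,
                    records = recs), json)
  }
  invisible(tbl)
}

#' Write the selected parsimonious model to YAML
#'
#' @param path_obj an `fr_regpath`.
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
write_parsimonious_yaml <- function(path_obj, path) {
  fit <- path_obj$final_fit
  yaml::write_yaml(list(lambda_star = path_obj$lambda_star,
                        alpha = path_obj$alpha,
                        positives = as.list(path_obj$positives),
                        log_p0 = as.list(fit$log_p0),
                        r = as.list(fit$r)), path)
  invisible(path)
}

write_manifest <- function(path, argv, inputs = character()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  json_write(list(argv = as.list(argv),
                  inputs_md5 = hashes,
                  package_version = as.character(utils::packageVersion("foldreg")),
                  r_version = R.version.string,
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
             path)
}

parse_method_list <- function(s) {
  specs <- list()
  for (tok in strsplit(s, ",", fixed = TRUE)[[1]]) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    fam <- switch(parts[1], l1 = "l1", lq = "lq", al = "adaptive_lasso",
                  en = "elastic_net",
                  stop("unknown method token '", parts[1], "'"))
    d <- if (length(parts) > 1) as.numeric(parts[2]) else 0
    specs[[parts[1]]] <- penalty_spec(fam, deformation = d)
  }
  specs
}

#' Command-line entry point
#'
#' Subcommands: `fit`, `scan`, `profile`, `benchmark`,
#' `deformation-scan`. Each writes its results plus a manifest (input
#' hashes, seed, configuration, versions) sufficient to reproduce the
#' run. Invoke through the shipped script
#' `system.file("cli", "foldreg.R", package = "foldreg")`.
#'
#' @param argv character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return integer exit code (0 on success), invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(argv) < 1)
      stop("usage: foldreg <fit|scan|profile|benchmark|deformation-scan> ...")
    sub <- argv[1]
    rest <- argv[-1]
    switch(sub,
           fit = cli_fit(rest),
           scan = cli_scan(rest),
           profile = cli_profile(rest),
           benchmark = cli_benchmark(rest),
           `deformation-scan` = cli_deformation(rest),
           stop("unknown subcommand '", sub, "'"))
    0L
  }, error = function(e) {
    message("foldreg error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

cli_parse <- function(args, option_list) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the command-line interface needs the 'optparse' package")
  parser <- optparse::OptionParser(option_list = option_list)
  optparse::parse_args(parser, args = args)
}

cli_fit <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--problem", type = "character"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n-starts", type = "integer", default = NULL,
                          dest = "n_starts"),
    optparse::make_option("--out", type = "character", default = "fit.json")))
  if (is.null(opt$problem)) stop("fit: --problem is required")
  bundle <- load_problem(opt$problem)
  fit <- fit_ml(bundle$problem, n_starts = opt$n_starts, seed = opt$seed)
  write_fit_json(fit, opt$out)
  write_manifest(paste0(opt$out, ".manifest.json"), c("fit", args),
                 opt$problem)
  message("wrote ", opt$out, " (chi2 = ", format(fit$value, digits = 8), ")")
}

cli_scan <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--problem", type = "character"),
    optparse::make_option("--penalty", type = "character", default = "l1"),
    optparse::make_option("--deformation", type = "double", default = 0),
    optparse::make_option("--lambda-min", type = "double", default = 1e-4,
                          dest = "lambda_min"),
    optparse::make_option("--lambda-max", type = "double", default = 1e6,
                          dest = "lambda_max"),
    optparse::make_option("--n-lambda", type = "integer", default = 41L,
                          dest = "n_lambda"),
    optparse::make_option("--alpha", type = "double", default = 0.95),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out-prefix", type = "character",
                          default = "scan", dest = "out_prefix")))
  if (is.null(opt$problem)) stop("scan: --problem is required")
  fam <- switch(opt$penalty, l1 = "l1", lq = "lq", al = "adaptive_lasso",
                en = "elastic_net", opt$penalty)
  spec <- penalty_spec(fam, deformation = opt$deformation)
  bundle <- load_problem(opt$problem)
  grid <- default_lambda_grid(opt$n_lambda, opt$lambda_min, opt$lambda_max)
  sc <- scan_lambda(bundle$problem, spec, grid, alpha = opt$alpha,
                    seed = opt$seed)
  write_regpath(sc, tsv = paste0(opt$out_prefix, "_path.tsv"),
                json = paste0(opt$out_prefix, "_path.json"))
  write_parsimonious_yaml(sc, paste0(opt$out_prefix, "_model.yaml"))
  write_manifest(paste0(opt$out_prefix, "_manifest.json"),
                 c("scan", args), opt$problem)
  message("lambda* = ", format(sc$lambda_star, digits = 6), "; positives: ",
          paste(sc$positives, collapse = ", "))
}

cli_profile <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--problem", type = "character"),
    optparse::make_option("--parameter", type = "character"),
    optparse::make_option("--alpha", type = "double", default = 0.95),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out-prefix", type = "character",
                          default = "profile", dest = "out_prefix")))
  if (is.null(opt$problem) || is.null(opt$parameter))
    stop("profile: --problem and --parameter are required")
  bundle <- load_problem(opt$problem)
  fit <- fit_ml(bundle$problem, seed = opt$seed)
  pr <- profile_likelihood(bundle$problem, fit, opt$parameter,
                           alpha = opt$alpha)
  readr::write_tsv(tidy.fr_profile(pr), paste0(opt$out_prefix, ".tsv"))
  json_write(as.list(glance.fr_profile(pr)), paste0(opt$out_prefix, "_ci.json"))
  write_manifest(paste0(opt$out_prefix, "_manifest.json"),
                 c("profile", args), opt$problem)
}

cli_benchmark <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--n-runs", type = "integer", default = 150L,
                          dest = "n_runs"),
    optparse::make_option("--methods", type = "character",
                          default = "l1,lq:0.2,al:0.2,en:0.08"),
    optparse::make_option("--n-lambda", type = "integer", default = 41L,
                          dest = "n_lambda"),
    optparse::make_option("--seed", type = "integer", default = 7L),
    optparse::make_option("--out", type = "character", default = "study")))
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  study <- run_study(opt$n_runs, parse_method_list(opt$methods),
                     seed = opt$seed,
                     lambda_grid = default_lambda_grid(opt$n_lambda),
                     progress = TRUE)
  readr::write_tsv(study$metrics, file.path(opt$out, "metrics.tsv"))
  readr::write_tsv(study$summary, file.path(opt$out, "summary.tsv"))
  readr::write_tsv(study$deltas, file.path(opt$out, "deltas.tsv"))
  json_write(study$config, file.path(opt$out, "config.json"))
  write_manifest(file.path(opt$out, "manifest.json"), c("benchmark", args))
}

cli_deformation <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--problem", type = "character"),
    optparse::make_option("--family", type = "character", default = "lq"),
    optparse::make_option("--d-grid", type = "character",
                          default = "0,0.1,0.2,0.4,0.6,0.8", dest = "d_grid"),
    optparse::make_option("--n-lambda", type = "integer", default = 41L,
                          dest = "n_lambda"),
    optparse::make_option("--alpha", type = "double", default = 0.95),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out-prefix", type = "character",
                          default = "deformation", dest = "out_prefix")))
  if (is.null(opt$problem)) stop("deformation-scan: --problem is required")
  fam <- switch(opt$family, lq = "lq", al = "adaptive_lasso",
                en = "elastic_net", opt$family)
  bundle <- load_problem(opt$problem)
  ds <- deformation_scan(bundle$problem, fam,
                         as.numeric(strsplit(opt$d_grid, ",")[[1]]),
                         default_lambda_grid(opt$n_lambda),
                         alpha = opt$alpha, seed = opt$seed)
  readr::write_tsv(dplyr::select(ds$results, -"positives", -"estimates"),
                   paste0(opt$out_prefix, ".tsv"))
  readr::write_tsv(tidy.fr_deformation_scan(ds),
                   paste0(opt$out_prefix, "_estimates.tsv"))
  write_manifest(paste0(opt$out_prefix, "_manifest.json"),
                 c("deformation-scan", args), opt$problem)
}
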