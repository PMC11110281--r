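#' Load and validate a model configuration
#'
#' Reads the YAML model configuration: one [uncertain_parameter()] per
#' model input (survival parameters, annual costs, utilities, disutilities,
#' adverse-event proportions, discount rate, willingness-to-pay, horizon),
#' the per-strategy wiring (which parameters feed which arm, oral vs
#' intravenous route), optional links between parameters for probabilistic
#' sampling (the intervention's medication price scales with the exchange
#' rate), and the published base-case cost decomposition used by
#' [person_time_from_costs()].
#'
#' The shipped default (`system.file("extdata", "table1.yaml",
#' package = "psmcea")`) carries the full base-case input set: log-normal
#' OS/PFS parameters per arm, 2022 NT$ annual costs, utilities 0.76 (PF) and
#' 0.68 (PP), a 3% annual discount rate, a 10-year horizon with 1-month
#' cycles, and a willingness-to-pay of NT$2,925,582 per QALY.
#'
#' @param path Path to a YAML configuration; defaults to the shipped file.
#' @return An object of class `model_config` with elements `params` (named
#'   list of `uncertain_parameter`), `strategies`, `intervention`,
#'   `psa_links`, `psa_iterations`, `published_costs`, `source`.
#' @export
load_model_config <- function(path = default_config_path()) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (field in c("strategies", "parameters"))
    if (is.null(raw[[field]]))
      stop("configuration is missing the '", field, "' section", call. = FALSE)

  params <- list()
  for (nm in names(raw$parameters)) {
    entry <- raw$parameters[[nm]]
    if (is.null(entry$value))
      stop("parameter '", nm, "' has no 'value' field", call. = FALSE)
    psa_family <- "fixed"; psa_params <- NULL
    if (!is.null(entry$psa)) {
      psa_family <- entry$psa$family
      if (!psa_family %in% c("normal", "gamma", "beta", "uniform", "fixed"))
        stop("parameter '", nm, "': unknown PSA family '", psa_family, "'",
             call. = FALSE)
      psa_params <- entry$psa$params
    }
    params[[nm]] <- uncertain_parameter(
      name = nm, value = entry$value,
      dsa_low = if (is.null(entry$dsa)) NA_real_ else entry$dsa[[1]],
      dsa_high = if (is.null(entry$dsa)) NA_real_ else entry$dsa[[2]],
      psa_family = psa_family, psa_params = psa_params,
      units = if (is.null(entry$units)) "" else entry$units)
  }

  strategies <- raw$strategies
  for (id in names(strategies)) {
    st <- strategies[[id]]
    for (field in c("label", "route", "os", "pfs", "med_cost", "nonmed_cost",
                    "ae_rate"))
      if (is.null(st[[field]]))
        stop("strategy '", id, "' is missing field '", field, "'", call. = FALSE)
    if (!st$route %in% c("oral", "intravenous"))
      stop("strategy '", id, "': route must be 'oral' or 'intravenous'",
           call. = FALSE)
    refs <- c(unlist(st$os$params), unlist(st$pfs$params),
              st$med_cost, st$nonmed_cost, st$ae_rate)
    missing <- setdiff(refs, names(params))
    if (length(missing))
      stop("strategy '", id, "' references undefined parameter(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  cfg <- structure(list(
    params = params,
    strategies = strategies,
    intervention = if (is.null(raw$intervention)) names(strategies)[1]
                   else raw$intervention,
    psa_links = raw$psa_links,
    psa_iterations = if (is.null(raw$psa_iterations)) 1000L
                     else as.integer(raw$psa_iterations),
    published_costs = raw$published_costs,
    source = path), class = "model_config")
  problems <- validate_model_config(cfg)
  if (length(problems))
    stop("invalid model configuration:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  cfg
}

#' @rdname load_model_config
#' @export
default_config_path <- function() {
  system.file("extdata", "table1.yaml", package = "psmcea", mustWork = TRUE)
}

#' Validate a model configuration
#'
#' Checks the economic invariants (utility ordering and bounds, non-negative
#' disutilities and costs, discount rate within its deterministic range,
#' adverse-event proportions in `[0, 1]`, positive log-normal scale
#' parameters) and returns a plain-text report.
#'
#' @param cfg A `model_config`.
#' @return Character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_model_config <- function(cfg) {
  v <- param_values(cfg)
  problems <- character(0)
  need <- c("u_pf", "u_pp", "d_ae", "d_iv", "supportive_cost",
            "discount_rate", "wtp_per_qaly", "horizon_years",
            "cycle_length_years")
  absent <- setdiff(need, names(v))
  if (length(absent))
    return(paste("missing mandatory parameter:", absent))
  if (v["u_pf"] < 0 || v["u_pf"] > 1) problems <- c(problems, "u_pf outside [0, 1]")
  if (v["u_pp"] < 0 || v["u_pp"] > 1) problems <- c(problems, "u_pp outside [0, 1]")
  if (v["u_pp"] > v["u_pf"])
    problems <- c(problems, "u_pp exceeds u_pf (post-progression utility above progression-free)")
  if (v["d_ae"] < 0 || v["d_iv"] < 0)
    problems <- c(problems, "disutilities must be non-negative")
  if (v["discount_rate"] < 0 || v["discount_rate"] > 0.05)
    problems <- c(problems, "discount_rate outside [0, 0.05]")
  if (v["horizon_years"] <= 0) problems <- c(problems, "horizon_years must be positive")
  if (v["cycle_length_years"] <= 0) problems <- c(problems, "cycle_length_years must be positive")
  for (id in names(cfg$strategies)) {
    st <- cfg$strategies[[id]]
    if (v[st$med_cost] < 0 || v[st$nonmed_cost] < 0)
      problems <- c(problems, paste0("strategy '", id, "': costs must be non-negative"))
    ae <- v[st$ae_rate]
    if (ae < 0 || ae > 1)
      problems <- c(problems, paste0("strategy '", id, "': ae_rate outside [0, 1]"))
    for (ep in c("os", "pfs")) {
      fam <- st[[ep]]$family
      pv <- v[unlist(st[[ep]]$params)]
      ok <- tryCatch({parametric_survival(fam, pv); TRUE},
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok))
        problems <- c(problems, paste0("strategy '", id, "' ", ep, ": ", ok))
    }
  }
  problems
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config: %d strategies, %d parameters, %d PSA iterations>\n",
              length(x$strategies), length(x$params), x$psa_iterations))
  cat(" strategies:", paste(vapply(x$strategies, `[[`, "", "label"),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Base-case values of every parameter
#' @param cfg A `model_config`.
#' @return Named numeric vector.
#' @export
param_values <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  vapply(cfg$params, `[[`, numeric(1), "value")
}

#' Replace base-case parameter values
#'
#' Returns a copy of the configuration with the named values substituted;
#' used by the deterministic and probabilistic sensitivity analyses.
#' DSA-range invariants are not re-imposed on the substituted values (a
#' sensitivity analysis deliberately pushes parameters to their bounds).
#'
#' @param cfg A `model_config`.
#' @param values Named numeric vector; names must be existing parameters.
#' @return A modified `model_config`.
#' @export
config_with <- function(cfg, values) {
  stopifnot(inherits(cfg, "model_config"))
  unknown <- setdiff(names(values), names(cfg$params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (nm in names(values)) cfg$params[[nm]]$value <- values[[nm]]
  cfg
}

#' Write a model configuration back to YAML
#'
#' Inverse of [load_model_config()]: a written configuration re-loads to
#' identical values.
#'
#' @param cfg A `model_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "model_config"))
  pars <- lapply(cfg$params, function(p) {
    out <- list(value = p$value)
    if (!is.na(p$dsa_low)) out$dsa <- c(p$dsa_low, p$dsa_high)
    if (p$psa_family != "fixed")
      out$psa <- list(family = p$psa_family, params = p$psa_params)
    if (nzchar(p$units)) out$units <- p$units
    out
  })
  doc <- list(intervention = cfg$intervention,
              psa_iterations = cfg$psa_iterations,
              strategies = cfg$strategies,
              parameters = pars,
              psa_links = cfg$psa_links,
              published_costs = cfg$published_costs)
  doc <- doc[!vapply(doc, is.null, logical(1))]
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

# economic settings (named list) from a value vector
econ_from_values <- function(v) {
  list(u_pf = unname(v["u_pf"]), u_pp = unname(v["u_pp"]),
       d_ae = unname(v["d_ae"]), d_iv = unname(v["d_iv"]),
       supportive_cost = unname(v["supportive_cost"]),
       discount_rate = unname(v["discount_rate"]),
       wtp = unname(v["wtp_per_qaly"]),
       horizon = unname(v["horizon_years"]),
       cycle = unname(v["cycle_length_years"]))
}

# strategy spec (named list) for one arm from a value vector
strategy_from_values <- function(cfg, id, v, price_multiplier = 1) {
  st <- cfg$strategies[[id]]
  mult <- if (id == cfg$intervention) price_multiplier else 1
  list(id = id, label = st$label, route = st$route,
       med_cost = unname(v[st$med_cost]),
       nonmed_cost = unname(v[st$nonmed_cost]),
       ae_rate = unname(v[st$ae_rate]),
       price_multiplier = mult,
       os = parametric_survival(st$os$family, v[unlist(st$os$params)]),
       pfs = parametric_survival(st$pfs$family, v[unlist(st$pfs$params)]))
}
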