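#' State occupancy trace of the partitioned survival model
#'
#' The three-state model derives occupancy directly from the two survival
#' curves at every cycle boundary: progression-free
#' \eqn{pf(t) = \min(PFS(t), OS(t))} (the cap guards against crossing
#' curves), post-progression \eqn{pp(t) = OS(t) - pf(t)}, dead
#' \eqn{1 - OS(t)}.  No transition probabilities are involved.
#'
#' @param os,pfs [survival_curve()] objects (time in months).
#' @param horizon Model horizon in years.
#' @param cycle Cycle length in years (default one month).
#' @return A `state_trace`: data frame with columns `time` (months), `pf`,
#'   `pp`, `dead`; occupancies sum to 1 at every boundary.
#' @export
build_trace <- function(os, pfs, horizon, cycle = 1 / 12) {
  stopifnot(inherits(os, "survival_curve"), inherits(pfs, "survival_curve"),
            horizon > 0, cycle > 0)
  t_yr <- seq(0, horizon, by = cycle)
  if (t_yr[length(t_yr)] < horizon) t_yr <- c(t_yr, horizon)
  t_mo <- t_yr * 12
  s_os <- eval_curve(os, t_mo)
  s_pf <- pmin(eval_curve(pfs, t_mo), s_os)
  out <- data.frame(time = t_mo, pf = s_pf, pp = s_os - s_pf, dead = 1 - s_os)
  class(out) <- c("state_trace", "data.frame")
  out
}

#' Discounted person-time in each alive state
#'
#' Trapezoid integration of the occupancy columns over the cycle grid with
#' a continuous annual discount factor \eqn{(1+r)^{-t}}.
#'
#' @param trace A [build_trace()] result.
#' @param rate Annual discount rate.
#' @return A `person_time` object: list with `pf_years` and `pp_years`
#'   (discounted person-years).
#' @export
person_time <- function(trace, rate = 0) {
  stopifnot(inherits(trace, "state_trace"), rate >= 0)
  t_yr <- trace$time / 12
  disc <- (1 + rate)^(-t_yr)
  structure(list(pf_years = trapezoid(t_yr, trace$pf * disc),
                 pp_years = trapezoid(t_yr, trace$pp * disc)),
            class = "person_time")
}

#' Person-time from a published cost decomposition
#'
#' The accrual step is linear in person-time, so it inverts exactly:
#' discounted progression-free person-years equal the progression-free
#' state cost divided by the annual progression-free rate (medication +
#' non-medication), and post-progression person-years equal the remaining
#' cost divided by the annual supportive-care rate.  This recovers the
#' person-time implied by a published base-case cost table when the
#' underlying (hybrid) survival curves are not available.
#'
#' @param cost_pf Discounted progression-free state cost (NT$).
#' @param cost_total Discounted overall cost (NT$).
#' @param strat A strategy spec as built inside [run_base_case()] (list
#'   with `med_cost`, `nonmed_cost`, `price_multiplier`).
#' @param econ Economic settings (list with `supportive_cost`).
#' @return A `person_time` object.
#' @export
person_time_from_costs <- function(cost_pf, cost_total, strat, econ) {
  pf_rate <- strat$med_cost * strat$price_multiplier + strat$nonmed_cost
  stopifnot(pf_rate > 0, econ$supportive_cost > 0, cost_total >= cost_pf)
  structure(list(pf_years = cost_pf / pf_rate,
                 pp_years = (cost_total - cost_pf) / econ$supportive_cost),
            class = "person_time")
}

#' @export
print.person_time <- function(x, ...) {
  cat(sprintf("<person_time: PF %.5f, PP %.5f discounted person-years>\n",
              x$pf_years, x$pp_years))
  invisible(x)
}

#' Accrue discounted costs, life-years and QALYs for one strategy
#'
#' Costs: treatment (medication x price multiplier + non-medication)
#' accrues while progression-free, supportive care while post-progression.
#' QALYs: progression-free person-time is weighted by the utility net of the
#' route disutility (intravenous administration only) and the
#' adverse-event disutility times the per-cycle grade >= 3 event
#' proportion; post-progression person-time by the post-progression
#' utility.  Life-years are the same person-times with unit weight.
#'
#' @param pt A [person_time()] result.
#' @param strat Strategy spec (list with `med_cost`, `nonmed_cost`,
#'   `price_multiplier`, `ae_rate`, `route`, `label`).
#' @param econ Economic settings (list with `u_pf`, `u_pp`, `d_ae`, `d_iv`,
#'   `supportive_cost`).
#' @return A `strategy_outcome`: list with `cost_pf`, `cost_pp`,
#'   `cost_total`, `ly_pf`, `ly_pp`, `ly_total`, `qaly_pf`, `qaly_pp`,
#'   `qaly_total`, `label`.
#' @export
accrue_outcomes <- function(pt, strat, econ) {
  stopifnot(inherits(pt, "person_time"))
  u_eff <- econ$u_pf - econ$d_iv * (strat$route == "intravenous") -
    econ$d_ae * strat$ae_rate
  if (u_eff < 0)
    stop("effective progression-free utility is negative for strategy '",
         strat$label, "'", call. = FALSE)
  cost_pf <- pt$pf_years * (strat$med_cost * strat$price_multiplier +
                              strat$nonmed_cost)
  cost_pp <- pt$pp_years * econ$supportive_cost
  structure(list(
    label = strat$label,
    cost_pf = cost_pf, cost_pp = cost_pp, cost_total = cost_pf + cost_pp,
    ly_pf = pt$pf_years, ly_pp = pt$pp_years,
    ly_total = pt$pf_years + pt$pp_years,
    qaly_pf = pt$pf_years * u_eff,
    qaly_pp = pt$pp_years * econ$u_pp,
    qaly_total = pt$pf_years * u_eff + pt$pp_years * econ$u_pp
  ), class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome: %s>\n", x$label))
  cat(sprintf("  cost  PF %12.0f  PP %10.0f  total %12.0f NT$\n",
              x$cost_pf, x$cost_pp, x$cost_total))
  cat(sprintf("  LY    PF %12.3f  PP %10.3f  total %12.3f\n",
              x$ly_pf, x$ly_pp, x$ly_total))
  cat(sprintf("  QALY  PF %12.3f  PP %10.3f  total %12.3f\n",
              x$qaly_pf, x$qaly_pp, x$qaly_total))
  invisible(x)
}

#' Evaluate the full base case
#'
#' Builds the survival curves from the configuration (pure parametric by
#' default; hybrid KM + extrapolation curves may be supplied per strategy),
#' runs the partitioned survival model, accrues outcomes, and compares the
#' intervention against every comparator.
#'
#' @param cfg A [load_model_config()] result.
#' @param price_multiplier Scales the intervention's medication cost
#'   (scenario hook; in (0, 1]).
#' @param conversion_factor Scales the non-medication (progression-free)
#'   and supportive-care (post-progression) cost rates; 1 in the base case
#'   where one reimbursement point equals NT$1.
#' @param horizon_years Optional horizon override (years).
#' @param wtp Optional willingness-to-pay override (NT$ per effectiveness
#'   unit).
#' @param metric `"qaly"` (default) or `"ly"` as the effectiveness measure
#'   in the pairwise comparisons.
#' @param person_times Optional named list of [person_time()] objects (one
#'   per strategy id) that bypasses the survival curves -- used to evaluate
#'   outcomes at externally derived person-time, e.g. from
#'   [person_time_from_costs()].  Note the person-time is taken as given:
#'   a `price_multiplier` then rescales costs but not occupancy.
#' @param curves Optional named list (per strategy id) of lists with
#'   elements `os` and/or `pfs` ([survival_curve()] objects) overriding the
#'   parametric curves, e.g. hybrids from [build_hybrid_curve()].
#' @return A `base_case` object: list with `outcomes` (per strategy),
#'   `comparisons` (named list of [compare()] results, intervention vs each
#'   comparator), `person_times`, `settings`.
#' @export
run_base_case <- function(cfg, price_multiplier = 1, conversion_factor = 1,
                          horizon_years = NULL, wtp = NULL, metric = "qaly",
                          person_times = NULL, curves = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  v <- param_values(cfg)
  run_base_case_values(cfg, v, price_multiplier = price_multiplier,
                       conversion_factor = conversion_factor,
                       horizon_years = horizon_years, wtp = wtp,
                       metric = metric, person_times = person_times,
                       curves = curves)
}

# core evaluator on an explicit parameter-value vector (shared with the
# sensitivity analyses, which perturb values without copying the config)
run_base_case_values <- function(cfg, v, price_multiplier = 1,
                                 conversion_factor = 1, horizon_years = NULL,
                                 wtp = NULL, metric = "qaly",
                                 person_times = NULL, curves = NULL) {
  if (price_multiplier <= 0 || price_multiplier > 1)
    stop("price_multiplier must lie in (0, 1]", call. = FALSE)
  metric <- match.arg(metric, c("qaly", "ly"))
  econ <- econ_from_values(v)
  if (!is.null(horizon_years)) econ$horizon <- horizon_years
  if (!is.null(wtp)) econ$wtp <- wtp
  econ$supportive_cost <- econ$supportive_cost * conversion_factor

  ids <- names(cfg$strategies)
  outcomes <- list()
  pts <- list()
  for (id in ids) {
    strat <- strategy_from_values(cfg, id, v, price_multiplier)
    strat$nonmed_cost <- strat$nonmed_cost * conversion_factor
    if (!is.null(person_times)) {
      pt <- person_times[[id]]
      if (is.null(pt)) stop("no person_time supplied for strategy '", id, "'",
                            call. = FALSE)
    } else {
      os_curve <- curves[[id]]$os %||% as_survival_curve(strat$os)
      pfs_curve <- curves[[id]]$pfs %||% as_survival_curve(strat$pfs)
      trace <- build_trace(os_curve, pfs_curve, econ$horizon, econ$cycle)
      pt <- person_time(trace, econ$discount_rate)
    }
    pts[[id]] <- pt
    outcomes[[id]] <- accrue_outcomes(pt, strat, econ)
  }

  comparators <- setdiff(ids, cfg$intervention)
  comparisons <- lapply(comparators, function(id)
    compare(outcomes[[cfg$intervention]], outcomes[[id]], wtp = econ$wtp,
            metric = metric))
  names(comparisons) <- comparators
  structure(list(outcomes = outcomes, comparisons = comparisons,
                 person_times = pts,
                 settings = c(econ, list(price_multiplier = price_multiplier,
                                         conversion_factor = conversion_factor,
                                         metric = metric))),
            class = "base_case")
}

#' @export
print.base_case <- function(x, ...) {
  cat("Partitioned survival model - base case\n")
  for (o in x$outcomes) print(o)
  for (nm in names(x$comparisons)) {
    cat(sprintf("-- vs %s --\n", nm))
    print(x$comparisons[[nm]])
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
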