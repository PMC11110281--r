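#' Pairwise cost-effectiveness comparison
#'
#' Computes the incremental cost, incremental effect, incremental
#' cost-effectiveness ratio (ICER = \eqn{\Delta C / \Delta E}) and
#' incremental net monetary benefit
#' (INMB = \eqn{\Delta E \cdot WTP - \Delta C}) of an intervention against a
#' comparator.  When the increments favour opposite directions the ICER is
#' replaced by a dominance flag: `"intervention dominant"` (cheaper and
#' more effective) or `"intervention dominated"`; with zero incremental
#' effect the ICER is undefined but the INMB is still returned.
#'
#' @param intervention,comparator [accrue_outcomes()] results on the same
#'   effectiveness metric.
#' @param wtp Willingness-to-pay threshold (NT$ per effectiveness unit).
#' @param metric `"qaly"` or `"ly"`.
#' @return A `cea_result`: list with `delta_cost`, `delta_effect`, `icer`
#'   (`NA` when flagged), `dominance` (`"none"`, `"intervention dominant"`,
#'   `"intervention dominated"`, `"undefined"`), `inmb`, `wtp`, `metric`,
#'   `labels`.
#' @export
compare <- function(intervention, comparator, wtp, metric = "qaly") {
  stopifnot(inherits(intervention, "strategy_outcome"),
            inherits(comparator, "strategy_outcome"), wtp >= 0)
  metric <- match.arg(metric, c("qaly", "ly"))
  eff <- if (metric == "qaly") "qaly_total" else "ly_total"
  dc <- intervention$cost_total - comparator$cost_total
  de <- intervention[[eff]] - comparator[[eff]]
  dominance <- "none"
  icer <- NA_real_
  if (de == 0) {
    dominance <- "undefined"
  } else if (dc < 0 && de > 0) {
    dominance <- "intervention dominant"
  } else if (dc > 0 && de < 0) {
    dominance <- "intervention dominated"
  } else {
    icer <- dc / de
  }
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 dominance = dominance, inmb = de * wtp - dc, wtp = wtp,
                 metric = metric,
                 labels = c(intervention$label, comparator$label)),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result: %s vs %s (%s)>\n", x$labels[1], x$labels[2],
              toupper(x$metric)))
  cat(sprintf("  delta cost %12.0f NT$   delta effect %7.4f\n",
              x$delta_cost, x$delta_effect))
  if (x$dominance == "none") {
    cat(sprintf("  ICER %14.0f NT$/%s\n", x$icer, toupper(x$metric)))
  } else {
    cat(sprintf("  ICER: %s\n", x$dominance))
  }
  cat(sprintf("  INMB %14.0f NT$ at WTP %.0f\n", x$inmb, x$wtp))
  invisible(x)
}

#' Scenario analyses
#'
#' Re-evaluates the full pipeline under each scenario: a stepwise price
#' reduction of the intervention's medication cost (multipliers 0.9 down to
#' 0.4 of the hypothesized price), a reimbursement-point conversion factor
#' of 0.9 applied to the non-medication and supportive-care cost rates,
#' alternative horizons of 5 and 15 years, and life-years instead of QALYs
#' as the effectiveness measure.  Because incremental cost is affine in the
#' price multiplier while effects are unchanged, the price-grid ICERs form
#' an exact arithmetic progression.
#'
#' @param cfg A [load_model_config()] result.
#' @param kinds Subset of `c("price_grid", "conversion_factor", "horizon",
#'   "ly_effectiveness")`; default all.
#' @param price_multipliers Price grid (default `seq(0.9, 0.4, by = -0.1)`).
#' @param conversion_factor Factor for the conversion-factor scenario.
#' @param horizons Alternative horizons in years.
#' @param person_times Optional externally derived person-time (see
#'   [run_base_case()]); horizon scenarios are skipped in that mode since
#'   occupancy cannot be re-integrated.
#' @return A `scenario_table` data frame with one row per scenario x
#'   comparator: `scenario`, `comparator`, `icer`, `inmb`, `delta_cost`,
#'   `delta_effect`; the base case is always the first rows.
#' @export
run_scenarios <- function(cfg,
                          kinds = c("price_grid", "conversion_factor",
                                    "horizon", "ly_effectiveness"),
                          price_multipliers = seq(0.9, 0.4, by = -0.1),
                          conversion_factor = 0.9,
                          horizons = c(5, 15),
                          person_times = NULL) {
  kinds <- match.arg(kinds, several.ok = TRUE,
                     choices = c("price_grid", "conversion_factor",
                                 "horizon", "ly_effectiveness"))
  if (any(price_multipliers <= 0 | price_multipliers > 1))
    stop("price multipliers must lie in (0, 1]", call. = FALSE)
  rows <- list()
  add <- function(name, bc) {
    for (cm in names(bc$comparisons)) {
      r <- bc$comparisons[[cm]]
      rows[[length(rows) + 1]] <<- data.frame(
        scenario = name, comparator = cm, icer = r$icer, inmb = r$inmb,
        delta_cost = r$delta_cost, delta_effect = r$delta_effect)
    }
  }
  add("base case", run_base_case(cfg, person_times = person_times))
  if ("price_grid" %in% kinds) {
    for (m in price_multipliers) {
      pt_m <- person_times   # person-time is exogenous in inversion mode
      add(sprintf("%.0f%% price", 100 * m),
          run_base_case(cfg, price_multiplier = m, person_times = pt_m))
    }
  }
  if ("conversion_factor" %in% kinds)
    add(sprintf("conversion factor %.2f", conversion_factor),
        run_base_case(cfg, conversion_factor = conversion_factor,
                      person_times = person_times))
  if ("horizon" %in% kinds && is.null(person_times)) {
    for (h in horizons)
      add(sprintf("horizon %g years", h),
          run_base_case(cfg, horizon_years = h))
  }
  if ("ly_effectiveness" %in% kinds)
    add("life-years as effectiveness",
        run_base_case(cfg, metric = "ly", person_times = person_times))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scenario_table", "data.frame")
  out
}

#' Write a scenario table as tab-separated text
#' @param x A [run_scenarios()] result.
#' @param path Output path.
#' @export
write_scenario_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
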