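#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each parameter with a deterministic range to its lower and upper
#' bound, all other parameters held at base case, and records the resulting
#' ICER of the intervention against the chosen comparator.  Survival
#' parameter ranges are the 95% confidence bounds (mean +/- 1.96 SE);
#' cost and utility ranges are +/-25% where no interval was available.
#' Parameters without a range are skipped with a warning (the per-cycle
#' adverse-event proportions carry no range by default; set
#' `include_ae = TRUE` to add them at +/-25%).
#'
#' @param cfg A [load_model_config()] result.
#' @param comparator Strategy id to compare against (default the first
#'   non-intervention strategy).
#' @param parameters Parameters to vary; defaults to every ranged parameter
#'   that enters the base-case model (the scenario-only conversion factor
#'   and the discount rate's structural range are included).
#' @param include_ae Also vary the adverse-event proportions at +/-25%.
#' @return A `tornado_table` data frame sorted by decreasing bar width:
#'   `parameter`, `low`, `high` (input bounds), `icer_low`, `icer_high`
#'   (ICER at each bound), `width` (`|icer_high - icer_low|`), with the
#'   base-case ICER in attribute `"base_icer"`.
#' @export
run_dsa <- function(cfg, comparator = NULL, parameters = NULL,
                    include_ae = FALSE) {
  stopifnot(inherits(cfg, "model_config"))
  comparator <- comparator %||% setdiff(names(cfg$strategies),
                                        cfg$intervention)[1]
  v0 <- param_values(cfg)
  base <- run_base_case_values(cfg, v0)$comparisons[[comparator]]$icer

  if (is.null(parameters)) {
    has_range <- vapply(cfg$params, function(p) !is.na(p$dsa_low), logical(1))
    parameters <- names(cfg$params)[has_range]
    # the conversion factor only acts in its scenario; exclude from the
    # base-case tornado
    parameters <- setdiff(parameters, "conversion_factor")
  }
  ae_names <- grep("^ae_rate_", names(cfg$params), value = TRUE)
  if (include_ae) parameters <- union(parameters, ae_names)

  rows <- list()
  for (nm in parameters) {
    p <- cfg$params[[nm]]
    if (is.null(p)) {
      warning("unknown parameter '", nm, "' skipped", call. = FALSE)
      next
    }
    lo <- p$dsa_low; hi <- p$dsa_high
    if (is.na(lo)) {
      if (nm %in% ae_names) {
        lo <- 0.75 * p$value; hi <- 1.25 * p$value
      } else {
        warning("parameter '", nm, "' has no DSA range; skipped", call. = FALSE)
        next
      }
    }
    icer_at <- function(x) {
      v <- v0; v[nm] <- x
      run_base_case_values(cfg, v)$comparisons[[comparator]]$icer
    }
    il <- icer_at(lo); ih <- icer_at(hi)
    rows[[nm]] <- data.frame(parameter = nm, low = lo, high = hi,
                             icer_low = il, icer_high = ih,
                             width = abs(ih - il))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base
  attr(out, "comparator") <- comparator
  class(out) <- c("tornado_table", "data.frame")
  out
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Each iteration draws every non-fixed parameter independently from its
#' sampling distribution (survival log-normal parameters from normals on
#' their estimates, costs from gammas, utilities and the adverse-event
#' disutility from betas, the exchange rate from a uniform), applies the
#' parameter links (the intervention's medication price scales with the
#' drawn exchange rate), rebuilds the survival curves and accrual, and
#' records total cost, QALYs and life-years per strategy.  Scale parameters
#' (`sdlog`) are redrawn if non-positive; redraw counts are recorded.
#' Results are fully reproducible from the seed.
#'
#' @param cfg A [load_model_config()] result.
#' @param n Number of iterations (default the configured count, 1000).
#' @param seed Integer seed.
#' @param price_multiplier Optional price scenario applied inside every
#'   iteration.
#' @return A `psa_result`: list with matrices `cost`, `qaly`, `ly`
#'   (n x strategies), data frame `draws` of sampled parameter values,
#'   `n`, `seed`, `redraws`.
#' @export
run_psa <- function(cfg, n = NULL, seed = 1L, price_multiplier = 1) {
  stopifnot(inherits(cfg, "model_config"))
  n <- as.integer(n %||% cfg$psa_iterations)
  stopifnot(n >= 1)
  set.seed(seed)
  v0 <- param_values(cfg)
  sampled <- names(cfg$params)[vapply(cfg$params, function(p)
    p$psa_family != "fixed", logical(1))]
  # the conversion factor is sampled only in its own scenario
  sampled <- setdiff(sampled, "conversion_factor")
  positive <- grepl("_sdlog$", sampled)

  draws <- matrix(NA_real_, n, length(sampled),
                  dimnames = list(NULL, sampled))
  redraws <- 0L
  for (j in seq_along(sampled)) {
    x <- draw_parameter(cfg$params[[sampled[j]]], n, positive = positive[j])
    redraws <- redraws + (attr(x, "redraws") %||% 0L)
    draws[, j] <- x
  }

  ids <- names(cfg$strategies)
  cost <- qaly <- ly <- matrix(NA_real_, n, length(ids),
                               dimnames = list(NULL, ids))
  for (i in seq_len(n)) {
    v <- v0
    v[sampled] <- draws[i, ]
    # linked parameters: price fixed in USD, converted at the drawn rate
    for (nm in names(cfg$psa_links)) {
      link <- cfg$psa_links[[nm]]$scales_with
      v[nm] <- v0[nm] * v[link] / v0[link]
    }
    bc <- run_base_case_values(cfg, v, price_multiplier = price_multiplier)
    for (id in ids) {
      cost[i, id] <- bc$outcomes[[id]]$cost_total
      qaly[i, id] <- bc$outcomes[[id]]$qaly_total
      ly[i, id] <- bc$outcomes[[id]]$ly_total
    }
  }
  structure(list(cost = cost, qaly = qaly, ly = ly,
                 draws = as.data.frame(draws), n = n, seed = seed,
                 redraws = redraws,
                 intervention = cfg$intervention,
                 wtp = unname(v0["wtp_per_qaly"])),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result: %d iterations, seed %d, strategies %s>\n",
              x$n, x$seed, paste(colnames(x$cost), collapse = ", ")))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of iterations in which
#' each strategy attains the highest net monetary benefit
#' (NMB = effect x WTP - cost).  Ties split their probability mass equally
#' among the tied strategies, so the fractions sum to one at every WTP.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Vector of willingness-to-pay values (NT$ per unit).
#' @param strategies Subset of strategy ids (default all); a two-strategy
#'   subset gives the pairwise curve against one comparator.
#' @param metric `"qaly"` or `"ly"`.
#' @return A `ceac_table` data frame: `wtp` plus one probability column per
#'   strategy.
#' @export
ceac <- function(psa, wtp_grid, strategies = NULL, metric = "qaly") {
  stopifnot(inherits(psa, "psa_result"), length(wtp_grid) >= 1)
  metric <- match.arg(metric, c("qaly", "ly"))
  strategies <- strategies %||% colnames(psa$cost)
  eff <- psa[[metric]][, strategies, drop = FALSE]
  cost <- psa$cost[, strategies, drop = FALSE]
  out <- matrix(0, length(wtp_grid), length(strategies),
                dimnames = list(NULL, strategies))
  for (g in seq_along(wtp_grid)) {
    nmb <- eff * wtp_grid[g] - cost
    best <- nmb == apply(nmb, 1, max)
    out[g, ] <- colSums(best / rowSums(best)) / nrow(nmb)
  }
  res <- data.frame(wtp = wtp_grid, out, check.names = FALSE)
  class(res) <- c("ceac_table", "data.frame")
  res
}

#' Expected value of perfect information (per person)
#'
#' EVPI = E[max over strategies of NMB] - max over strategies of E[NMB]:
#' the expected gain from resolving all parameter uncertainty before
#' choosing.  It is zero exactly when a single strategy attains the maximum
#' NMB in every iteration, and never negative.
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness-to-pay (NT$ per unit).
#' @param strategies Subset of strategy ids (default all).
#' @param metric `"qaly"` or `"ly"`.
#' @return EVPI in NT$ per person.
#' @export
evpi <- function(psa, wtp, strategies = NULL, metric = "qaly") {
  stopifnot(inherits(psa, "psa_result"), length(wtp) == 1, wtp >= 0)
  metric <- match.arg(metric, c("qaly", "ly"))
  strategies <- strategies %||% colnames(psa$cost)
  nmb <- psa[[metric]][, strategies, drop = FALSE] * wtp -
    psa$cost[, strategies, drop = FALSE]
  max(0, mean(apply(nmb, 1, max)) - max(colMeans(nmb)))
}

#' Pairwise PSA summary against one comparator
#'
#' Incremental cost and effect per iteration plus the headline PSA
#' quantities reported per comparison: the fraction of iterations in the
#' first quadrant of the cost-effectiveness plane (more effective, more
#' costly), the probability the intervention is cost-effective at the
#' willingness-to-pay (positive INMB), and the pairwise EVPI.
#'
#' @param psa A [run_psa()] result.
#' @param comparator Comparator strategy id.
#' @param wtp Willingness-to-pay; defaults to the configured threshold.
#' @param metric `"qaly"` or `"ly"`.
#' @return List with `delta_cost`, `delta_effect` (length-n vectors),
#'   `first_quadrant`, `prob_cost_effective`, `evpi`, `wtp`.
#' @export
compare_psa <- function(psa, comparator, wtp = NULL, metric = "qaly") {
  stopifnot(inherits(psa, "psa_result"))
  metric <- match.arg(metric, c("qaly", "ly"))
  wtp <- wtp %||% psa$wtp
  iv <- psa$intervention
  dc <- psa$cost[, iv] - psa$cost[, comparator]
  de <- psa[[metric]][, iv] - psa[[metric]][, comparator]
  inmb <- de * wtp - dc
  list(delta_cost = dc, delta_effect = de,
       first_quadrant = mean(dc > 0 & de > 0),
       prob_cost_effective = mean(inmb > 0),
       evpi = evpi(psa, wtp, strategies = c(iv, comparator), metric = metric),
       wtp = wtp)
}
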