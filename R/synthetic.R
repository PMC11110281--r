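#' Synthetic trial fixture
#'
#' Describes one simulated trial arm: the true log-normal (or other
#' parametric) OS and PFS distributions, the sample size, and the accrual
#' and follow-up windows that generate administrative censoring.  The
#' defaults emulate the second-line cholangiocarcinoma trials feeding the
#' model: per-arm sample sizes of a few hundred, accrual over 24 months and
#' a further 24 months of follow-up.
#'
#' @param name Arm identifier.
#' @param os,pfs [parametric_survival()] distributions (months).
#' @param n Number of patients (>= 10).
#' @param accrual_months Uniform accrual window length.
#' @param followup_months Additional follow-up after accrual closes; a
#'   patient entering at time `a` is administratively censored at
#'   `accrual_months + followup_months - a`.
#' @param seed Integer seed making the fixture reproducible.
#' @return An object of class `trial_fixture`.
#' @export
trial_fixture <- function(name, os, pfs, n = 300, accrual_months = 24,
                          followup_months = 24, seed = 1L) {
  stopifnot(inherits(os, "parametric_survival"),
            inherits(pfs, "parametric_survival"))
  if (n < 10) stop("a trial fixture needs at least 10 patients", call. = FALSE)
  if (accrual_months < 0 || followup_months <= 0)
    stop("infeasible accrual/follow-up windows", call. = FALSE)
  structure(list(name = name, os = os, pfs = pfs, n = as.integer(n),
                 accrual_months = accrual_months,
                 followup_months = followup_months, seed = as.integer(seed)),
            class = "trial_fixture")
}

#' Generate correlated OS/PFS individual patient data
#'
#' Draws per-patient (OS, PFS) pairs with `PFS <= OS` by construction: a
#' shared uniform drives both marginals through their quantile functions
#' (comonotone coupling), and the PFS draw is truncated at the OS draw.
#' Uniform accrual plus a fixed study end produce administrative right
#' censoring; both endpoints are censored at the same per-patient cutoff.
#'
#' @param fix A [trial_fixture()].
#' @return List with data frames `os_ipd` and `pfs_ipd` (columns `time`,
#'   `event`) and the uncensored `truth` (columns `os`, `pfs`, `cutoff`).
#' @export
generate_trial_ipd <- function(fix) {
  stopifnot(inherits(fix, "trial_fixture"))
  set.seed(fix$seed)
  u <- stats::runif(fix$n)
  os_t <- quantile_surv(fix$os, u)
  pfs_t <- pmin(quantile_surv(fix$pfs, u), os_t)
  entry <- stats::runif(fix$n, 0, fix$accrual_months)
  cutoff <- fix$accrual_months + fix$followup_months - entry
  os_ipd <- data.frame(time = pmin(os_t, cutoff),
                       event = as.integer(os_t <= cutoff))
  pfs_ipd <- data.frame(time = pmin(pfs_t, cutoff),
                        event = as.integer(pfs_t <= cutoff))
  list(os_ipd = os_ipd, pfs_ipd = pfs_ipd,
       truth = data.frame(os = os_t, pfs = pfs_t, cutoff = cutoff))
}

# quantile function: time t with S(t) = u  (u uniform -> survival times)
quantile_surv <- function(dist, u) {
  p <- dist$params
  switch(dist$family,
    exponential = stats::qexp(u, rate = p[1], lower.tail = FALSE),
    weibull     = stats::qweibull(u, shape = p[1], scale = p[2], lower.tail = FALSE),
    gompertz    = flexsurv::qgompertz(u, shape = p[1], rate = p[2], lower.tail = FALSE),
    loglogistic = flexsurv::qllogis(u, shape = p[1], scale = p[2], lower.tail = FALSE),
    lognormal   = stats::qlnorm(u, meanlog = p[1], sdlog = p[2], lower.tail = FALSE),
    gengamma    = flexsurv::qgengamma(u, mu = p[1], sigma = p[2], Q = p[3],
                                      lower.tail = FALSE))
}

#' Emulate curve digitization
#'
#' Samples the Kaplan-Meier step function of an IPD set on a regular time
#' grid, perturbs each reading with truncated-normal jitter (the noise a
#' plot-digitization workflow introduces), monotonizes the result, and
#' attaches the exact numbers-at-risk table and event total -- producing
#' the [digitized_curve()] that [reconstruct_ipd()] consumes.
#'
#' @param ipd Data frame with `time` (months) and `event` columns.
#' @param grid_step Reading interval in months (default 0.25).
#' @param jitter_sd Standard deviation of the reading noise on the
#'   probability scale (0 reproduces the KM values exactly).
#' @param risk_step Spacing of the numbers-at-risk table in months.
#' @param seed Integer seed for the jitter.
#' @return A [digitized_curve()].
#' @export
digitize_curve <- function(ipd, grid_step = 0.25, jitter_sd = 0,
                           risk_step = 3, seed = 1L) {
  stopifnot(grid_step > 0, jitter_sd >= 0, risk_step > 0)
  ipd <- validate_ipd(ipd)
  km <- km_estimate(ipd)
  t_max <- max(ipd$time)
  grid <- seq(0, t_max, by = grid_step)
  if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
  s <- eval_curve(km, grid)
  if (jitter_sd > 0) {
    set.seed(seed)
    s <- pmin(1, pmax(0, s + stats::rnorm(length(s), 0, jitter_sd)))
    s[1] <- 1
  }
  s <- cummin(s)
  rt_times <- seq(0, t_max, by = risk_step)
  risk_table <- data.frame(
    time = rt_times,
    n_risk = vapply(rt_times, function(x) sum(ipd$time >= x), integer(1)))
  digitized_curve(points = data.frame(time = grid, surv = s),
                  risk_table = risk_table,
                  total_events = sum(ipd$event))
}

#' Write a complete synthetic fixture bundle
#'
#' Writes, for each of the three arms parameterized by the shipped
#' configuration, the simulated OS and PFS individual patient data, the
#' digitized curves with risk tables, plus a copy of the model
#' configuration and a manifest of file checksums -- everything the
#' reconstruction -> fitting -> model -> CEA pipeline needs, in plain
#' delimited text.
#'
#' @param out_dir Output directory (created if absent).
#' @param cfg Model configuration supplying the true distributions.
#' @param n Patients per arm.
#' @param seed Integer seed.
#' @param jitter_sd Digitization noise (probability scale).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
make_fixture_bundle <- function(out_dir, cfg = load_model_config(), n = 300,
                                seed = 1L, jitter_sd = 0.003) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- param_values(cfg)
  files <- character(0)
  for (id in names(cfg$strategies)) {
    strat <- strategy_from_values(cfg, id, v)
    fix <- trial_fixture(id, strat$os, strat$pfs, n = n,
                         seed = seed + match(id, names(cfg$strategies)))
    ipd <- generate_trial_ipd(fix)
    for (ep in c("os", "pfs")) {
      dat <- ipd[[paste0(ep, "_ipd")]]
      f_ipd <- file.path(out_dir, sprintf("%s_%s_ipd.tsv", id, ep))
      write_ipd(dat, f_ipd)
      dg <- digitize_curve(dat, jitter_sd = jitter_sd, seed = fix$seed)
      f_pts <- file.path(out_dir, sprintf("%s_%s_digitized.tsv", id, ep))
      f_rt <- file.path(out_dir, sprintf("%s_%s_risktable.tsv", id, ep))
      write_digitized_curve(dg, f_pts, f_rt)
      files <- c(files, f_ipd, f_pts, f_rt)
    }
  }
  f_cfg <- file.path(out_dir, "table1.yaml")
  file.copy(cfg$source, f_cfg, overwrite = TRUE)
  files <- c(files, f_cfg)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
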