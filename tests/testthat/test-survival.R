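# reference parameter sets used across the survival tests
ref_dists <- list(
  exponential = parametric_survival("exponential", 0.1),
  weibull     = parametric_survival("weibull", c(1.3, 10)),
  gompertz    = parametric_survival("gompertz", c(0.05, 0.08)),
  loglogistic = parametric_survival("loglogistic", c(1.8, 8)),
  lognormal   = parametric_survival("lognormal", c(2.2773, 1.13)),
  gengamma    = parametric_survival("gengamma", c(2.2, 0.8, 0.5)))

test_that("all six families give proper survival functions", {
  grid <- c(0, 10^seq(-3, 2.2, length.out = 200))
  for (nm in names(ref_dists)) {
    s <- survival_probability(ref_dists[[nm]], grid)
    expect_equal(s[1], 1, label = paste(nm, "S(0)"))
    expect_true(all(diff(s) <= 1e-12), label = paste(nm, "monotone"))
    expect_true(all(s >= 0 & s <= 1), label = paste(nm, "bounded"))
  }
  expect_error(survival_probability(ref_dists$lognormal, -1), "non-negative")
  expect_error(parametric_survival("lognormal", c(1, -0.5)), "positive")
})

test_that("log-normal survival matches the normal-CDF closed form", {
  ln <- parametric_survival("lognormal", c(2.2773, 1.13))
  expect_equal(survival_probability(ln, exp(2.2773)), 0.5, tolerance = 1e-12)
  ln2 <- parametric_survival("lognormal", c(1.199, 1.049))
  expect_equal(survival_probability(ln2, 12),
               pnorm((log(12) - 1.199) / 1.049, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(survival_probability(ln2, 12), 0.1102, tolerance = 1e-3)
})

test_that("exponential MLE has its closed form on toy data", {
  fit <- fit_parametric(data.frame(time = c(1, 2, 3), event = 1), "exponential")
  expect_equal(unname(fit$dist$params["rate"]), 0.5, tolerance = 1e-6)
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
  expect_equal(fit$bic, log(3) - 2 * fit$loglik)
})

test_that("fitting requires events and positive times", {
  expect_error(fit_parametric(data.frame(time = c(1, 2), event = 0), "weibull"),
               "no events")
  expect_error(fit_parametric(data.frame(time = c(0, 2), event = 1), "weibull"),
               "strictly positive")
})

test_that("MLE recovers the truth within 3 SE for each family (n = 2000)", {
  for (nm in names(ref_dists)) {
    dist <- ref_dists[[nm]]
    fix <- trial_fixture(nm, os = dist, pfs = dist, n = 2000,
                         accrual_months = 0,
                         followup_months = quantile_surv_test(dist, 0.3),
                         seed = 42)
    ipd <- generate_trial_ipd(fix)$os_ipd
    expect_gt(mean(ipd$event == 0), 0.2)  # ~30% administrative censoring
    fit <- fit_parametric(ipd, nm)
    z <- abs(fit$dist$params - dist$params) / fit$dist$se
    expect_true(all(z < 3), label = sprintf(
      "%s estimates within 3 SE (z = %s)", nm,
      paste(round(z, 2), collapse = ", ")))
  }
})

test_that("AIC selection identifies log-normal data in a majority of seeds", {
  ln <- parametric_survival("lognormal", c(2.2773, 1.13))
  wins <- 0L
  for (seed in 1:20) {
    fix <- trial_fixture("ln", os = ln, pfs = ln, n = 300, accrual_months = 0,
                         followup_months = quantile_surv_test(ln, 0.25),
                         seed = seed)
    fits <- suppressWarnings(fit_all_families(generate_trial_ipd(fix)$os_ipd))
    if (select_best(fits)$family == "lognormal") wins <- wins + 1L
  }
  expect_gt(wins, 10L)
})

test_that("select_best minimizes AIC with a BIC tiebreak", {
  mk <- function(fam, aic, bic) {
    structure(list(dist = list(family = fam), loglik = 0, aic = aic, bic = bic),
              class = "fitted_model")
  }
  sel <- select_best(list(mk("a", 100, 101), mk("b", 90, 95), mk("c", 95, 91)))
  expect_identical(sel$family, "b")
  expect_identical(sel$by_bic, "c")
  expect_false(sel$agreement)
  tie <- select_best(list(mk("a", 90, 99), mk("b", 90, 91)))
  expect_identical(tie$family, "b")
  expect_error(select_best(list(mk("a", 1, 1))), "at least two")
})

test_that("hybrid curves equal KM before the cutoff and attach continuously", {
  ipd <- data.frame(time = c(2, 4, 6, 8, 9, 11), event = c(1, 1, 0, 1, 1, 0))
  km <- km_estimate(ipd)
  dist <- parametric_survival("lognormal", c(1.8, 0.9))
  hyb <- build_hybrid_curve(km, dist, cutoff = 8)
  for (t in c(0, 1, 3, 5, 7.9))
    expect_equal(eval_curve(hyb, t), eval_curve(km, t))
  expect_equal(eval_curve(hyb, 8 + 1e-9), eval_curve(hyb, 8), tolerance = 1e-6)
  # tail is the rescaled parametric curve
  expect_equal(eval_curve(hyb, 15),
               eval_curve(km, 8) * survival_probability(dist, 15) /
                 survival_probability(dist, 8))
  # identity case: KM taken from the parametric curve itself
  par_curve <- as_survival_curve(dist)
  hyb2 <- build_hybrid_curve(par_curve, dist, cutoff = 10)
  for (t in c(0.5, 5, 10, 20, 60))
    expect_equal(eval_curve(hyb2, t), survival_probability(dist, t),
                 tolerance = 1e-12)
  expect_error(build_hybrid_curve(km, dist, cutoff = 50), "beyond")
})

test_that("discounted person-time matches the exponential closed form", {
  expect_equal(discounted_state_time(survival_curve(function(t) rep(1, length(t))),
                                     horizon = 1, rate = 0), 1)
  lambda <- 0.9; rate <- 0.03; horizon <- 10
  curve <- survival_curve(function(t) exp(-lambda * t / 12))
  rho <- log(1 + rate)
  closed <- (1 - exp(-(lambda + rho) * horizon)) / (lambda + rho)
  grid_val <- discounted_state_time(curve, horizon, rate)
  expect_lt(abs(grid_val - closed) / closed, 0.001)
  expect_lt(grid_val, discounted_state_time(curve, horizon, 0))
})

test_that("trapezoid person-time has converged on the base-case curves", {
  cfg <- test_cfg()
  v <- param_values(cfg)
  for (id in names(cfg$strategies)) {
    for (ep in c("os", "pfs")) {
      pars <- v[unlist(cfg$strategies[[id]][[ep]]$params)]
      curve <- as_survival_curve(parametric_survival("lognormal", pars))
      a <- discounted_state_time(curve, 10, 0.03, cycle = 1 / 12)
      b <- discounted_state_time(curve, 10, 0.03, cycle = 1 / 24)
      expect_lt(abs(a - b) / b, 5e-4, label = paste(id, ep))
    }
  }
})
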