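test_that("tornado entries bracket the base case sensibly", {
  cfg <- test_cfg()
  td <- run_dsa(cfg, comparator = "mfolfox")
  base <- attr(td, "base_icer")
  # setting a parameter to its base value reproduces the base ICER
  v <- param_values(cfg)
  v["u_pp"] <- cfg$params$u_pp$value
  expect_equal(psmcea:::run_base_case_values(cfg, v)$comparisons$mfolfox$icer,
               base)
  # ICER is monotone increasing in the intervention's medication cost
  row <- td[td$parameter == "med_cost_ivosidenib", ]
  expect_lt(row$icer_low, base)
  expect_gt(row$icer_high, base)
  # parameters without a range are skipped with a warning
  expect_warning(run_dsa(cfg, "mfolfox", parameters = c("u_pp", "wtp_per_qaly")),
                 "no DSA range")
  # AE proportions join only on request, at +/-25%
  td_ae <- run_dsa(cfg, "mfolfox", include_ae = TRUE)
  expect_true("ae_rate_ivosidenib" %in% td_ae$parameter)
  expect_false("ae_rate_ivosidenib" %in% td$parameter)
  # sorted by bar width, widths consistent
  expect_true(all(diff(td$width) <= 0))
  expect_equal(td$width, abs(td$icer_high - td$icer_low))
})

test_that("medication cost and utilities are leading tornado drivers", {
  cfg <- test_cfg()
  for (cm in c("mfolfox", "fu_lv")) {
    td <- run_dsa(cfg, comparator = cm)
    top3 <- td$parameter[1:3]
    expect_true(all(c("med_cost_ivosidenib", "u_pp") %in% top3),
                label = sprintf("med cost and u_pp in top 3 vs %s", cm))
  }
})

test_that("PSA is reproducible and degenerates to the base case", {
  cfg <- test_cfg()
  a <- run_psa(cfg, n = 50, seed = 123)
  b <- run_psa(cfg, n = 50, seed = 123)
  expect_identical(a$cost, b$cost)
  expect_identical(a$qaly, b$qaly)
  expect_identical(a$draws, b$draws)
  c2 <- run_psa(cfg, n = 50, seed = 124)
  expect_false(identical(a$cost, c2$cost))
  # zero-variance distributions reproduce the base case exactly
  degenerate <- collapse_psa(cfg)
  d <- run_psa(degenerate, n = 5, seed = 1)
  bc <- run_base_case(cfg)
  for (id in colnames(d$cost)) {
    expect_equal(unname(d$cost[, id]), rep(bc$outcomes[[id]]$cost_total, 5))
    expect_equal(unname(d$qaly[, id]), rep(bc$outcomes[[id]]$qaly_total, 5))
  }
})

test_that("PSA sample means converge to the distribution means", {
  cfg <- test_cfg()
  psa <- run_psa(cfg, n = 1000, seed = 99)
  for (nm in colnames(psa$draws)) {
    p <- cfg$params[[nm]]
    m <- distribution_mean(p)
    sdev <- stats::sd(psa$draws[[nm]])
    expect_lt(abs(mean(psa$draws[[nm]]) - m), 3 * sdev / sqrt(psa$n) + 1e-12,
              label = sprintf("mean of %s", nm))
    # draws stay inside the distribution's support
    if (p$psa_family == "beta")
      expect_true(all(psa$draws[[nm]] > 0 & psa$draws[[nm]] < 1))
    if (p$psa_family == "gamma") expect_true(all(psa$draws[[nm]] > 0))
    if (p$psa_family == "uniform")
      expect_true(all(psa$draws[[nm]] >= p$psa_params[1] &
                        psa$draws[[nm]] <= p$psa_params[2]))
  }
  # scale parameters are never drawn non-positive
  expect_true(all(psa$draws$os_ivosidenib_sdlog > 0))
})

test_that("incremental draws fall in the first quadrant of the CE plane", {
  cfg <- test_cfg()
  psa <- run_psa(cfg, n = 1000, seed = 2024)
  for (cm in c("mfolfox", "fu_lv")) {
    ps <- compare_psa(psa, cm)
    expect_equal(ps$first_quadrant, 1,
                 label = sprintf("first-quadrant fraction vs %s", cm))
  }
})

test_that("probability of cost-effectiveness rises as the price falls", {
  cfg <- test_cfg()
  probs <- vapply(c(1, 0.7, 0.4), function(m) {
    psa <- run_psa(cfg, n = 300, seed = 31, price_multiplier = m)
    compare_psa(psa, "mfolfox")$prob_cost_effective
  }, numeric(1))
  expect_true(all(diff(probs) >= 0))
  expect_gt(probs[3], probs[1])
})

test_that("CEAC frequencies are exact on an enumerable toy PSA", {
  cost <- cbind(a = c(10, 10), b = c(0, 30))
  eff <- cbind(a = c(1, 1), b = c(0.5, 0.5))
  psa <- toy_psa(cost, eff)
  # wtp 0: cheaper wins -> b wins iter 1, a wins iter 2
  # wtp 20: iter 1 ties (NMB 10 each, split), iter 2 a wins -> a = 0.75
  # wtp 40: nmb_a = (30, 30); nmb_b = (20, -10) -> a wins both
  cc <- ceac(psa, wtp_grid = c(0, 20, 40))
  expect_equal(cc$a, c(0.5, 0.75, 1))
  expect_equal(cc$b, c(0.5, 0.25, 0))
  expect_true(all(abs(rowSums(cc[, c("a", "b")]) - 1) < 1e-12))
  # ties split equally
  tie <- toy_psa(cbind(a = 5, b = 5), cbind(a = 1, b = 1))
  cct <- ceac(tie, wtp_grid = 10)
  expect_equal(cct$a, 0.5)
  expect_equal(cct$b, 0.5)
  # wtp -> infinity: the higher-effect strategy wins
  big <- ceac(psa, wtp_grid = 1e12)
  expect_equal(big$a, 1)
})

test_that("CEAC columns sum to one on real PSA output", {
  cfg <- test_cfg()
  psa <- run_psa(cfg, n = 100, seed = 5)
  wtp <- param_values(cfg)["wtp_per_qaly"]
  cc <- ceac(psa, wtp_grid = c(0, wtp / 2, wtp, 2 * wtp))
  probs <- as.matrix(cc[, -1])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(cc)))
})

test_that("EVPI follows its enumeration oracle and is never negative", {
  # NMB pairs (10, 0) and (0, 10) at wtp 0 via negative costs
  psa <- toy_psa(cbind(a = c(-10, 0), b = c(0, -10)),
                 cbind(a = c(0, 0), b = c(0, 0)))
  expect_equal(evpi(psa, wtp = 0), 5)
  # one strategy wins every iteration -> EVPI 0
  psa2 <- toy_psa(cbind(a = c(0, 0), b = c(5, 7)), cbind(a = c(1, 1), b = c(1, 1)))
  expect_equal(evpi(psa2, wtp = 3), 0)
  cfg <- test_cfg()
  psa3 <- run_psa(cfg, n = 200, seed = 8)
  wtp_grid <- c(0, 1e6, 3e6, 1e7)
  for (w in wtp_grid) expect_gte(evpi(psa3, w), 0)
  # EVPI is 0 exactly when one strategy's CEAC value is 1
  cc <- ceac(psa3, wtp_grid)
  for (g in seq_along(wtp_grid)) {
    winner_always <- any(abs(as.matrix(cc[g, -1]) - 1) < 1e-12)
    expect_identical(evpi(psa3, wtp_grid[g]) == 0, winner_always,
                     label = sprintf("EVPI-CEAC duality at wtp %g", wtp_grid[g]))
  }
})
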