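# shared fixtures: the shipped configuration, a degenerate (zero-variance)
# copy for PSA identity checks, and a hand-built PSA result for enumeration
# oracles

test_cfg <- function() load_model_config()

# collapse every sampling distribution to a point mass at the base value
collapse_psa <- function(cfg) {
  for (nm in names(cfg$params)) {
    cfg$params[[nm]]$psa_family <- "fixed"
    cfg$params[[nm]]$psa_params <- NULL
  }
  cfg
}

# minimal psa_result with explicit cost/effect matrices (for CEAC/EVPI
# enumeration oracles)
toy_psa <- function(cost, effect, wtp = 1, intervention = colnames(cost)[1]) {
  structure(list(cost = cost, qaly = effect, ly = effect,
                 draws = data.frame(), n = nrow(cost), seed = 0L,
                 redraws = 0L, intervention = intervention, wtp = wtp),
            class = "psa_result")
}

# person-times implied by the published base-case cost decomposition
worked_example_pt <- function(cfg = test_cfg()) published_person_times(cfg)

# time at which a distribution's survival equals u (internal helper)
quantile_surv_test <- function(dist, u) psmcea:::quantile_surv(dist, u)
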