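# Base-case model inputs for the three-strategy partitioned survival model:
# log-normal OS/PFS parameters per arm (time in months), annual costs in
# 2022 NT$, utilities and disutilities, adverse-event proportions, discount
# rate, willingness-to-pay, and per-parameter uncertainty annotations
# (dsa: deterministic range; psa: sampling distribution).
intervention: ivosidenib
psa_iterations: 1000

strategies:
  ivosidenib:
    label: ivosidenib
    route: oral
    os:  {family: lognormal, params: [os_ivosidenib_meanlog, os_ivosidenib_sdlog]}
    pfs: {family: lognormal, params: [pfs_ivosidenib_meanlog, pfs_ivosidenib_sdlog]}
    med_cost: med_cost_ivosidenib
    nonmed_cost: nonmed_cost_ivosidenib
    ae_rate: ae_rate_ivosidenib
  mfolfox:
    label: mFOLFOX
    route: intravenous
    os:  {family: lognormal, params: [os_mfolfox_meanlog, os_mfolfox_sdlog]}
    pfs: {family: lognormal, params: [pfs_mfolfox_meanlog, pfs_mfolfox_sdlog]}
    med_cost: med_cost_mfolfox
    nonmed_cost: nonmed_cost_chemo
    ae_rate: ae_rate_mfolfox
  fu_lv:
    label: 5-FU/LV
    route: intravenous
    os:  {family: lognormal, params: [os_fu_lv_meanlog, os_fu_lv_sdlog]}
    pfs: {family: lognormal, params: [pfs_fu_lv_meanlog, pfs_fu_lv_sdlog]}
    med_cost: med_cost_fu_lv
    nonmed_cost: nonmed_cost_chemo
    ae_rate: ae_rate_fu_lv

parameters:
  # overall survival (log-normal; time in months)
  os_ivosidenib_meanlog: {value: 2.2773, dsa: [2.0715, 2.4831], psa: {family: normal, params: [2.2773, 0.105]}, units: log-months}
  os_ivosidenib_sdlog:   {value: 1.13,   dsa: [0.9665, 1.2935], psa: {family: normal, params: [1.13, 0.0834]}, units: log-months}
  os_mfolfox_meanlog:    {value: 1.8419, dsa: [1.6522, 2.0316], psa: {family: normal, params: [1.8419, 0.0968]}, units: log-months}
  os_mfolfox_sdlog:      {value: 0.8586, dsa: [0.7187, 0.9985], psa: {family: normal, params: [0.8586, 0.0714]}, units: log-months}
  os_fu_lv_meanlog:      {value: 1.7813, dsa: [1.6080, 1.9546], psa: {family: normal, params: [1.7813, 0.0884]}, units: log-months}
  os_fu_lv_sdlog:        {value: 0.792,  dsa: [0.6601, 0.9239], psa: {family: normal, params: [0.792, 0.0673]}, units: log-months}
  # progression-free survival (log-normal; time in months)
  pfs_ivosidenib_meanlog: {value: 1.199,  dsa: [0.9893, 1.4087], psa: {family: normal, params: [1.199, 0.107]}, units: log-months}
  pfs_ivosidenib_sdlog:   {value: 1.049,  dsa: [0.8785, 1.2195], psa: {family: normal, params: [1.049, 0.087]}, units: log-months}
  pfs_mfolfox_meanlog:    {value: 1.4414, dsa: [1.2809, 1.6019], psa: {family: normal, params: [1.4414, 0.0819]}, units: log-months}
  pfs_mfolfox_sdlog:      {value: 0.7361, dsa: [0.6205, 0.8517], psa: {family: normal, params: [0.7361, 0.059]}, units: log-months}
  pfs_fu_lv_meanlog:      {value: 0.8171, dsa: [0.5935, 1.0407], psa: {family: normal, params: [0.8171, 0.1141]}, units: log-months}
  pfs_fu_lv_sdlog:        {value: 1.0347, dsa: [0.8705, 1.1989], psa: {family: normal, params: [1.0347, 0.0838]}, units: log-months}
  # medication costs (per year); the intervention price is a hypothesized
  # NT$10,402 per 500 mg, sampled in PSA through the exchange rate only
  med_cost_ivosidenib: {value: 3744552, dsa: [2808414, 4680690], units: NT$/year}
  med_cost_mfolfox:    {value: 132708, units: NT$/year}
  med_cost_fu_lv:      {value: 26124, units: NT$/year}
  exchange_rate:       {value: 29.81, psa: {family: uniform, params: [27.93, 31.01]}, units: NT$/USD}
  # non-medication costs (per year, progression-free state)
  nonmed_cost_ivosidenib: {value: 291576, dsa: [218682, 364470], psa: {family: gamma, params: [16.56, 0.00006]}, units: NT$/year}
  nonmed_cost_chemo:      {value: 856986, dsa: [642740, 1071233], psa: {family: gamma, params: [59.94, 0.00007]}, units: NT$/year}
  # supportive care (per year, post-progression state)
  supportive_cost: {value: 497710, dsa: [373283, 622138], psa: {family: gamma, params: [69.3, 0.00014]}, units: NT$/year}
  # utilities and disutilities
  u_pf: {value: 0.76, dsa: [0.57, 0.95], psa: {family: beta, params: [4.7, 1.5]}, units: utility}
  u_pp: {value: 0.68, dsa: [0.51, 0.85], psa: {family: beta, params: [29, 13.6]}, units: utility}
  d_iv: {value: 0.025, dsa: [0.01875, 0.03125], units: disutility}
  d_ae: {value: 0.16, dsa: [0.12, 0.2], psa: {family: beta, params: [36, 193]}, units: disutility}
  # grade >= 3 adverse-event proportion per treatment cycle, PF state
  ae_rate_ivosidenib: {value: 0.192, units: probability}
  ae_rate_mfolfox:    {value: 0.048, units: probability}
  ae_rate_fu_lv:      {value: 0.013, units: probability}
  # settings
  discount_rate:      {value: 0.03, dsa: [0.0, 0.05], units: per-year}
  wtp_per_qaly:       {value: 2925582, units: NT$/QALY}
  horizon_years:      {value: 10, units: years}
  cycle_length_years: {value: 0.08333333333333333, units: years}
  conversion_factor:  {value: 0.9, dsa: [0.81, 0.99], psa: {family: uniform, params: [0.8, 1.0]}, units: dimensionless}

# in PSA the intervention's medication price moves proportionally with the
# drawn exchange rate (price fixed in USD, converted at the drawn rate)
psa_links:
  med_cost_ivosidenib: {scales_with: exchange_rate}

# published base-case discounted cost decomposition (NT$ per patient);
# dividing by the annual accrual rates recovers the discounted person-time
# each arm spent progression-free and post-progression
published_costs:
  ivosidenib: {pf: 2629218, total: 2945117}
  mfolfox:    {pf: 453061,  total: 599085}
  fu_lv:      {pf: 312157,  total: 466176}
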