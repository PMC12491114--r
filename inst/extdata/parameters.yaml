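# Base-case inputs for the two cohort cost-utility models.
# Times are months, costs are EUR per monthly cycle at the 2019-2022 claims
# price level, utilities are annual QALY weights.
model_config:
  horizon: 60            # monthly cycles
  cycle_length: 1        # months
  annual_discount: 0.03
  cohort_size: 1000
  within_cycle_correction: life_table
  progression_rule: pfs-direct
  third_line_clock: model

treatment_duration:      # tunnel months under treatment
  PRLT_SoC: 8
  SoC: 8
  CBZ: 7

third_line_mix:          # split of the cohort after first progression (Model II)
  SoC: 0.75
  PRLT_SoC: 0.25

survival:
  model_I:
    PRLT_SoC:
      os:  {family: loglogistic, shape: 1.9263, scale: 15.5377}
      pfs: {family: lognormal, meanlog: 2.1048, sdlog: 0.9841}
    SoC:
      os:  {family: gamma, shape: 1.6065, rate: 0.1140}
      pfs:
        knots: [3.6]
        segments:
          - {family: loglogistic, shape: 4.7332, scale: 2.3643}
          - {family: lognormal, meanlog: 2.2763, sdlog: 0.8268}
  model_II:
    PRLT_SoC:
      os:  {family: loglogistic, shape: 1.9576, scale: 18.6763}
      pfs: {family: lognormal, meanlog: 1.5854, sdlog: 0.9737}
    CBZ:
      os:  {family: loglogistic, shape: 2.2526, scale: 19.3004}
      pfs:
        knots: [4.5]
        segments:
          - {family: lognormal, meanlog: 0.4939, sdlog: 0.5765}
          - {family: lognormal, meanlog: 2.0563, sdlog: 0.2874}

# per-state values: cost (EUR/month), cost_sd (gamma SD for PSA),
# utility (annual weight), beta1/beta2 (beta shape parameters for PSA)
values:
  model_I:
    PRLT_SoC:
      treatment:   {cost: 7340, cost_sd: 2942, utility: 0.7492, beta1: 2.6590, beta2: 0.8901}
      stable:      {cost: 3990, cost_sd: 3099, utility: 0.7492, beta1: 2.6590, beta2: 0.8901}
      progression: {cost: 3990, cost_sd: 3099, utility: 0.6440, beta1: 1.8359, beta2: 1.0149}
    SoC:
      treatment:   {cost: 6716, cost_sd: 3818, utility: 0.6946, beta1: 1.7945, beta2: 0.7890}
      stable:      {cost: 4794, cost_sd: 4932, utility: 0.6946, beta1: 1.7945, beta2: 0.7890}
      progression: {cost: 4794, cost_sd: 4932, utility: 0.6460, beta1: 1.5734, beta2: 0.8622}
  model_II:
    PRLT_SoC:
      treatment:   {cost: 7340, cost_sd: 2942, utility: 0.7492, beta1: 2.6590, beta2: 0.8901}
      stable:      {cost: 3990, cost_sd: 3099, utility: 0.7492, beta1: 2.6590, beta2: 0.8901}
    CBZ:
      treatment:   {cost: 14460, cost_sd: 4760, utility: 0.7260, beta1: 1.2698, beta2: 0.4792}
      stable:      {cost: 8123, cost_sd: 12422, utility: 0.7260, beta1: 1.2698, beta2: 0.4792}
  # third-line values in Model II replicate the Model I rows per sub-strategy

dsa:                      # one-way ranges
  cost_factor: [0.5, 1.5]
  utility_factor: [0.75, 1.25]
  discount: [0.0, 0.05]
  horizon: [84, 120]

scenarios:
  commercial_price:
    description: >
      Commercial single-dose price for PRLT (German benefit assessment, 20%
      average rebate, added to mean inpatient costs) instead of the in-house
      production cost observed in the claims data.
    prlt_treatment_cost: 21303
  kreis_cbz_costs:
    description: >
      Cabazitaxel cost inputs from the older Kreis et al. claims analysis,
      updated to 2022 price levels; resource use while stable assumed at 55%
      of the under-treatment level.
    applies_to: [II]
    cbz_treatment_cost: 8718
    cbz_stable_cost: 4795
  radium223_soc:
    description: >
      SoC under-treatment cost blended assuming 59% of the SoC cost cohort
      received Radium-223 (at the observed 6,716 EUR/month) and 41% any other
      SoC treatment at 3,646 EUR/month.
    applies_to: [I]
    soc_treatment_blend: {share_radium: 0.59, cost_radium: 6716, cost_other: 3646}
  mix_25_75:               # 25% SoC / 75% PRLT third line
    applies_to: [II]
    third_line_mix: {SoC: 0.25, PRLT_SoC: 0.75}
  mix_100_0:               # 100% SoC third line
    applies_to: [II]
    third_line_mix: {SoC: 1.0, PRLT_SoC: 0.0}
  mix_0_100:               # 100% PRLT third line
    applies_to: [II]
    third_line_mix: {SoC: 0.0, PRLT_SoC: 1.0}
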