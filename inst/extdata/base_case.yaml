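diag_tilmanocept:
  sensitivity: 0.979
  specificity: 0.99
diag_sulfur:
  sensitivity: 0.727
  specificity: 0.99
prevalence: 0.28
transitions:
  ned_row_standard:
    NED->NED: 0.869
    NED->LR: 0.032
    NED->NR: 0.035
    NED->DM: 0.004
    NED->Dead: 0.061
  ned_row_fn:
    NED->NED: 0.749
    NED->LR: 0.007
    NED->NR: 0.137
    NED->DM: 0.003
    NED->Dead: 0.104
  lr_row:
    LR->LR: 0.614
    LR->DM: 0.286
    LR->Dead: 0.1
  nr_row:
    NR->NR: 0.589
    NR->DM: 0.286
    NR->Dead: 0.125
  dm_row:
    DM->DM: 0.837
    DM->Dead: 0.163
costs:
  agent_cost_tilmanocept: 628.0
  agent_cost_sulfur_colloid: 105.0
  primary_resection: 28512.0
  concurrent_neck_dissection: 3946.0
  salvage_neck_dissection: 29366.0
  radiation_therapy: 24693.0
  chemo_with_rt: 7684.0
  chemo_metastatic: 36619.0
  annual_cost_ned: 1579.0
  annual_cost_other_remission: 1071.0
  eol_care: 11101.0
utilities:
  utility_post_resection: 0.913
  disutility_neck_dissection: -0.072
  disutility_salvage: -0.238
  disutility_rt: -0.06
  disutility_chemo_rt: -0.09
  disutility_recurrent_metastatic: -0.343
p_rt_given_positive: 0.49
p_chemo_given_positive: 0.15
discount_rate: 0.03
horizon_years: 30
cycle_length_years: 1.0
wtp_threshold: 100000.0
structural_variant:
  reward_timing: start
  discount_timing: delayed
  dm_cost: entry
  recurrence_adjuvant: mix
  upfront_disutility: once
  half_cycle: no
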