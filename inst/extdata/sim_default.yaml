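version: 1
targets:
  any_wheeze: 0.165
  wheeze_ge2: 0.088
  bronchodilator: 0.098
  corticosteroid: 0.11
  ed_or_hosp: 0.035
  chart_high: 0.071
  chart_moderate: 0.238
  chart_low: 0.691
latent:
  p_prone: 0.07
wheeze3:
  prone:
    p_any: 0.9
    p_cont: 0.75
  nonprone:
    p_any: 0.109677419355
    p_cont: 0.399509803922
prior_wheeze:
  recent0:
    p0: 0.72754491018
    p1: 0.1
    cont: 0.45
  recent_pos:
    p_any: 0.5
    cont: 0.45
age3:
  mean: 3.08
  sd: 0.17
  min: 2.5
  max: 3.7
age5:
  mean: 5.08
  sd: 0.19
  min: 4.5
  max: 5.8
supporting:
  p_bronch:
  - 0.04
  - 0.21038961039
  - 0.55
  p_cort:
  - 0.059531736527
  - 0.223
  - 0.49
  p_both:
  - 0.039531736527
  - 0.08338961039
  - 0.262727272727
  p_ics_given_cort: 0.92
  p_ocs_given_cort: 0.18
  p_edh_given_med:
  - 0.04
  - 0.12
  - 0.360254385965
  p_edh_given_nomed:
  - 0.004
  - 0.02
  - 0.05
  p_hosp_given_edh: 0.22
  p_hosp_only_given_hosp: 0.3
  lambda_extra_ed: 0.4
  p_freq_cough:
  - 0.02
  - 0.05
  - 0.087003222342
  p_occ_cough:
  - 0.1
  - 0.2
  - 0.3
cough_episodes:
  p_one_given_none: 0.3
  lambda_occ: 1.0
  base_freq: 4.0
  lambda_freq: 2.0
atopy:
  parental_asthma:
    prone: 0.4
    nonprone: 0.21
  eczema_dx:
    prone: 0.3
    nonprone: 0.11
  aeroallergen_sensitized:
    prone: 0.35
    nonprone: 0.19
  food_sensitized:
    prone: 0.18
    nonprone: 0.095
  eosinophils_ge_4pct:
    prone: 0.3
    nonprone: 0.12
  wheeze_apart_from_colds:
  - 0.02
  - 0.35
  - 0.65
dx3:
  p_definite:
  - 0.012
  - 0.07
  - 0.1
  p_definite_band2_support: 0.5
  p_possible:
  - 0.045
  - 0.16
  - 0.28
  p_external:
    definite: 0.55
    possible: 0.12
    none: 0.008
persistence:
  intercept: -2.45916470683
  beta_support: 1.335287674002
  beta_prone: 1.3
  cont5: 0.45
  p_w5_one_nonpersist: 0.4
incident_wheeze5:
  p_any_prone: 0.55
  p_any_nonprone:
  - 0.09
  - 0.3
  cont: 0.45
asthma5:
  definite:
    intercept: -3.534140480671
    beta_high: 2.269397432128
    beta_prone: 1.6
  p_possible_by_category:
    low: 0.04
    moderate: 0.095
    high: 0.24
  p_external:
    definite: 0.75
    possible: 0.25
    none: 0.008
missingness:
  ed_hosp_block: 0.076
  dry_cough_without_cold: 0.002
  ics_use_last_12mo: 0.001
  ocs_use_last_12mo: 0.001
  bronchodilator_use_last_12mo: 0.001
  atopy_block: 0.012
  outcome_record: 0.063

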