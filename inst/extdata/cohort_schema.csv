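column,type,levels,min,max,block,required
child_id,character,,,,id,TRUE
age_years,numeric,,0.5,10,symptoms3,TRUE
wheeze_episodes_last_12mo,count,,0,365,symptoms3,TRUE
wheeze_episodes_prior,count,,0,365,symptoms3,TRUE
dry_cough_without_cold,ordinal,none|occasional|frequent,,,symptoms3,TRUE
cough_episodes_last_12mo,count,,0,365,symptoms3,TRUE
ics_use_last_12mo,logical,,,,symptoms3,TRUE
ocs_use_last_12mo,logical,,,,symptoms3,TRUE
bronchodilator_use_last_12mo,logical,,,,symptoms3,TRUE
ed_visits_wheeze_last_12mo,count,,0,365,symptoms3,TRUE
hospitalizations_wheeze_last_12mo,count,,0,365,symptoms3,TRUE
parental_asthma,logical,,,,atopy,FALSE
eczema_dx,logical,,,,atopy,FALSE
aeroallergen_sensitized,logical,,,,atopy,FALSE
food_sensitized,logical,,,,atopy,FALSE
eosinophils_ge_4pct,logical,,,,atopy,FALSE
wheeze_apart_from_colds,logical,,,,atopy,FALSE
asthma_dx_in_study,ordinal,definite|possible|none,,,dx3,FALSE
asthma_dx_external,logical,,,,dx3,FALSE
out5_age_years,numeric,,0.5,12,outcome5,FALSE
out5_wheeze_episodes_last_12mo,count,,0,365,outcome5,FALSE
out5_asthma_dx_in_study,ordinal,definite|possible|none,,,outcome5,FALSE
out5_asthma_dx_external,logical,,,,outcome5,FALSE
out5_ics_use,logical,,,,outcome5,FALSE
out5_ocs_use,logical,,,,outcome5,FALSE
out5_bronchodilator_use,logical,,,,outcome5,FALSE
out5_ed_or_hosp_wheeze,logical,,,,outcome5,FALSE
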