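rule_version,recent_wheeze_band,prior_wheeze_band,any_supporting_criterion,category,rule_id,follow_up
1,2+,0,1,high,high_recent_wheeze_with_support,further_evaluation_now
1,2+,1,1,high,high_recent_wheeze_with_support,further_evaluation_now
1,2+,2+,1,high,high_recent_wheeze_with_support,further_evaluation_now
1,2+,0,0,moderate,moderate_recent_wheeze_no_support,reassess_6_months
1,2+,1,0,moderate,moderate_recent_wheeze_no_support,reassess_6_months
1,2+,2+,0,moderate,moderate_recent_wheeze_no_support,reassess_6_months
1,1,0,1,moderate,moderate_single_recent_wheeze,reassess_6_months
1,1,1,1,moderate,moderate_single_recent_wheeze,reassess_6_months
1,1,2+,1,moderate,moderate_single_recent_wheeze,reassess_6_months
1,1,0,0,moderate,moderate_single_recent_wheeze,reassess_6_months
1,1,1,0,moderate,moderate_single_recent_wheeze,reassess_6_months
1,1,2+,0,moderate,moderate_single_recent_wheeze,reassess_6_months
1,0,0,1,low,low_no_recent_wheeze,reassess_12_months
1,0,1,1,low,low_no_recent_wheeze,reassess_12_months
1,0,2+,1,moderate,moderate_remote_recurrent_wheeze,reassess_6_months
1,0,0,0,low,low_no_recent_wheeze,reassess_12_months
1,0,1,0,low,low_no_recent_wheeze,reassess_12_months
1,0,2+,0,moderate,moderate_remote_recurrent_wheeze,reassess_6_months
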