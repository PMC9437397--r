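# Estimated percentage of school children (age 6-17 years) requiring
# eye-care services, by GBD super region and condition group, with the
# published cluster-survey sample sizes where available. Prevalences are
# stored as printed (rounded to 0.1%); the published sample sizes were
# computed from unrounded inputs and are not all recoverable from these
# rounded values (see ?reproduce_tables).
region,condition_group,prevalence_percent,printed_sample_size
South-East Asia East Asia & Oceania,vision_impairment_all_causes,17.0,1126
South-East Asia East Asia & Oceania,vi_uncorrected_refractive_error,16.5,NA
South-East Asia East Asia & Oceania,non_vision_impairing_conditions,1.9,NA
South-East Asia East Asia & Oceania,total_all_conditions,18.9,988
Sub-Saharan Africa,vision_impairment_all_causes,2.0,10777
Sub-Saharan Africa,vi_uncorrected_refractive_error,0.9,NA
Sub-Saharan Africa,non_vision_impairing_conditions,1.9,NA
Sub-Saharan Africa,total_all_conditions,3.9,5675
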