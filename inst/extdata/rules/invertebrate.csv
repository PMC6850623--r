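trophic_level,species_group,statistic_kinds,percent_min,percent_max,effect_tokens,duration_min_hours,duration_max_hours,designation
invertebrate,Daphnia|Ceriodaphnia,EC|LC,5,70,mortality|intoxication,,48,acute
invertebrate,any,LC|EC|IC,5,70,mortality|intoxication|filtration rate|abundance,,96,acute
invertebrate,any,NOEC|LOEC|MATC,,,reproduction|growth|mortality|emergence|population growth|abundance,168,,chronic
invertebrate,any,EC|IC,5,20,reproduction|growth|emergence,168,,chronic
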