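trophic_level,species_group,statistic_kinds,percent_min,percent_max,effect_tokens,duration_min_hours,duration_max_hours,designation
fish,any,LC|EC,5,70,mortality,,96,acute
fish,any,LC|EC|IC,5,70,intoxication,,96,acute
fish,any,NOEC|LOEC|MATC,,,growth|reproduction|hatchability|mortality,168,,chronic
fish,any,EC|IC,5,20,growth|reproduction|hatchability,168,,chronic
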