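trophic_level,species_group,statistic_kinds,percent_min,percent_max,effect_tokens,duration_min_hours,duration_max_hours,designation
amphibian,any,LC|EC,5,70,mortality|intoxication|teratogenesis,,96,acute
amphibian,any,LC|EC,5,70,mortality,,168,acute
amphibian,any,NOEC|LOEC|MATC,,,growth|mortality|teratogenesis|reproduction|hatchability,168,,chronic
amphibian,any,EC|IC,5,20,growth|hatchability,168,,chronic
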