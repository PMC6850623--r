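trophic_level,species_group,statistic_kinds,percent_min,percent_max,effect_tokens,duration_min_hours,duration_max_hours,designation
algae,any,EC|IC,5,70,growth|biomass|cells|chlorophyll|population growth|primary production|gross primary productivity|population change|population reduction|abundance|nitrogen fixation,24,96,acute
algae,any,LC,5,70,mortality,24,96,acute
algae,any,NOEC|LOEC|MATC,,,growth|biomass|cells|chlorophyll|population growth|primary production|abundance,24,,chronic
algae,any,EC|IC,5,20,growth|biomass|cells|chlorophyll|population growth,24,,chronic
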