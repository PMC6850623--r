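alias,canonical
survival,mortality
mort,mortality
growth rate,growth
specific growth rate,growth
weight,growth
length,growth
repro,reproduction
offspring,reproduction
cell count,cells
cell number,cells
immobilization,intoxication
immobilisation,intoxication
hatch,hatchability
hatching,hatchability
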