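taxon,taxon_rank,plant_height,sla,seed_mass,srl
Festuca rubra,species,0.45,16.2,1.05,180
Trifolium repens,species,0.15,22.8,0.62,110
Calluna vulgaris,species,0.35,9.8,0.03,95
Vaccinium,genus,0.30,14.5,0.25,120
Plantago,genus,0.25,18.9,1.8,75
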