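plot_id,species,genus,cover
P00001,Festuca rubra,Festuca,45
P00001,Trifolium repens,Trifolium,20
P00001,Plantago lanceolata,Plantago,10
P00002,Calluna vulgaris,Calluna,70
P00002,Vaccinium myrtillus,Vaccinium,25
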