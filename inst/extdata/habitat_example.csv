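plot_id,level1,level2,level3
P00001,R,R1,R1.1
P00002,S,S2,S2.2
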