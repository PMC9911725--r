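plot_id,latitude,longitude,survey_year,abundance_type
P00001,51.234,10.567,2004,cover
P00002,60.112,14.890,1998,cover
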