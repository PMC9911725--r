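plot_id,bio1,bio2,bio3,bio4,bio5,bio6,bio7,bio8,bio9,bio10,bio11,bio12,bio13,bio14,bio15,bio16,bio17,bio18,bio19
P00001,1.02,0.63,3.29,2.79,3.37,7.1,6.76,8.74,8.05,10.93,10.4,11.33,11.73,13.31,14.9,14.15,17.97,16.62,19.36
P00002,0.82,1.4,3.39,3.64,4.74,6.76,7.99,8.09,8.8,10.48,8.81,9.88,12.63,13.13,14.75,15.92,17.18,16.56,17.24
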