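climatic_region,PFC1,PFC2a,PFC2b,PFC3
Mediterranean,8313,6093,1290,561
Transitional Mediterranean,0,317,633,939
Transitional Temperate,2377,3931,3005,1285
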