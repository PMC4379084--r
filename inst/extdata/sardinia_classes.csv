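pfc,n_fires,area_km2,sigma_published
PFC1,10690,4210.25,1.98
PFC2a,10341,5759.63,1.40
PFC2b,4928,5743.31,0.67
PFC3,2785,6691.31,0.32
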