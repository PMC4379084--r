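clc_type,PFC1,PFC2a,PFC2b,PFC3
Urban areas,852,880,353,110
Arable lands,5921,3350,754,129
Permanent crops,521,760,216,27
Heterogeneous agricultural areas,2598,3324,1699,673
Forests,176,242,334,872
Natural grasslands and pastures,241,808,386,71
Shrublands,381,977,1186,903
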