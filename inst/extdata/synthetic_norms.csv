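measurement,age_low_years,age_high_years,mean,sd
bcr,0,0.5,0.08,0.015
bcr,0.5,1,0.082,0.015
bcr,1,2,0.084,0.015
bcr,2,4,0.086,0.015
bcr,4,8,0.088,0.015
bcr,8,14,0.092,0.015
bcr,14,20,0.096,0.015
pons,0,0.5,14,1.5
pons,0.5,1,16,1.5
pons,1,2,18,1.8
pons,2,4,20,2
pons,4,8,21.5,2
pons,8,14,23,2.2
pons,14,20,24,2.5
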