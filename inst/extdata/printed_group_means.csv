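cohort,contrast,shape,mean_pre,sd_pre,mean_post,sd_post,printed_reduction_pct
cadaveric,laterality,cylinder,0.436,0.107,0.227,0.055,47.9
cadaveric,laterality,sphere,0.493,0.121,0.286,0.082,42.0
cadaveric,laterality,plane,0.438,0.119,0.225,0.063,48.6
clinical,laterality,cylinder,0.366,0.111,0.183,0.037,50.0
clinical,laterality,sphere,0.451,0.136,0.236,0.069,47.7
clinical,laterality,plane,0.390,0.144,0.192,0.048,50.8
cadaveric,sp_inclusion,cylinder,0.472,0.107,0.394,0.089,16.5
cadaveric,sp_inclusion,sphere,0.539,0.119,0.440,0.099,18.4
cadaveric,sp_inclusion,plane,0.498,0.111,0.368,0.087,26.1
clinical,sp_inclusion,cylinder,0.418,0.116,0.315,0.078,24.6
clinical,sp_inclusion,sphere,0.527,0.136,0.375,0.082,28.8
clinical,sp_inclusion,plane,0.488,0.138,0.292,0.054,40.2
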