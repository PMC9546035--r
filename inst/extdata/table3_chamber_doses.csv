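chamber,field_id,dose_gy,sdom_gy,ratio_printed,u_ratio_printed
advanced_markus,5x6,7.694,0.053,1.005,0.007
advanced_markus,5x8,7.710,0.054,1.003,0.007
advanced_markus,5x10,7.769,0.054,1.006,0.007
advanced_markus,5x12,7.701,0.054,0.995,0.007
advanced_markus,6x5,7.685,0.053,1.002,0.007
advanced_markus,12x5,7.746,0.054,1.001,0.007
ppc05,5x6,7.923,0.055,1.035,0.007
ppc05,5x8,7.954,0.056,1.034,0.007
ppc05,5x10,7.968,0.056,1.031,0.007
ppc05,5x12,7.971,0.056,1.030,0.007
ppc05,6x5,7.934,0.055,1.035,0.007
ppc05,12x5,7.991,0.056,1.032,0.007
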