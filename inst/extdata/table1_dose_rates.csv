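nozzle_current_na,dose_rate_gy_s,dose_rate_sd_gy_s
20,5.1,0.3
40,10.6,0.6
70,19.5,1.0
80,30.8,1.5
105,40.2,1.7
135,52.1,2.3
160,61.7,2.9
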