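field_id,dose_gy,expanded_uncertainty_pct_k1
5x6,7.654,1.50
5x8,7.690,1.50
5x10,7.726,1.50
5x12,7.736,1.50
6x5,7.666,1.50
12x5,7.741,1.50
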