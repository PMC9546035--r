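chamber,serial,qp_linear_nc,u_qp_linear_nc,qp_curve_nc,u_qp_curve_nc,difference_pct,u_difference_pct
advanced_markus,1728,5.030,0.016,5.033,0.019,0.06,0.49
ppc05,949,12.591,0.040,12.627,0.098,0.29,0.84
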