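abbrev,p_max,ci_pmax,A_mag,ci_A,k_s,ci_k,reduced_r2
CL,0.91,0.01,0.41,0.04,15.00,2.55,0.95
DF,0.93,0.01,0.42,0.03,23.24,3.33,0.96
RKTA,0.94,0.01,0.44,0.03,12.72,1.62,0.97
ML,0.90,0.01,0.40,0.06,11.13,3.16,0.89
AA,0.78,0.02,0.28,0.06,15.39,6.53,0.57
TMSRK,0.82,0.02,0.32,0.05,28.50,9.98,0.78
PRK,0.88,0.02,0.38,0.05,26.07,7.02,0.86
MAPP,0.74,0.02,0.24,0.06,26.87,14.81,0.63
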