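abbrev,P_kPa,dHvap_kJmol,relative_vp_vs_RK
CL,7.54e-6,82.7,5
DF,1.06e-4,70.4,65
RKTA,9.95e-4,63.4,589
ML,9.59e-6,82.2,6
AA,5.73e-4,67.1,349
TMSRK,4.56e-4,69.4,278
PRK,3.81e-5,79.8,23
MAPP,7.06e-5,79.1,43
RK,1.80e-6,93.9,1
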