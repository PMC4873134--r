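abbrev,compound,A,B,C,T_valid_low,T_valid_high
CL,4-(4-acetoxyphenyl)-2-butanone,9.32104,4291.92,-0.998176,498.0,587.4
DF,"4-(4-(2,2-difluoroacetoxy)phenyl)-2-butanone",8.24451,3609.15,-2.78829,500.7,581.2
RKTA,"4-(4-(2,2,2-trifluoroacetoxy)phenyl)-2-butanone",7.85832,3164.11,-6.80614,458.2,547.4
ML,4-(4-formyloxyphenyl)-2-butanone,10.0050,4670.01,12.7001,489.2,563.7
AA,4-(4-methoxyphenyl)-2-butanone,7.47561,2912.97,-26.3452,475.5,559.2
TMSRK,4-(4-((trimethylsilyl)oxy)phenyl)-2-butanone,7.14615,2697.19,-40.9688,479.0,566.2
PRK,4-(4-propionyloxyphenyl)-2-butanone,7.47995,3021.15,-44.2637,509.9,596.4
MAPP,methyl 3-(4-acetoxyphenyl)propionate,7.32341,2832.29,-51.3238,499.0,584.7
RK,4-(4-hydroxyphenyl)-2-butanone,8.86245,3867.82,-33.3688,506.1,597.2
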