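abbrev,compound,has_phenolic_ester,has_butanone_chain,in_bioassay
CL,4-(4-acetoxyphenyl)-2-butanone,TRUE,TRUE,TRUE
DF,"4-(4-(2,2-difluoroacetoxy)phenyl)-2-butanone",TRUE,TRUE,TRUE
RKTA,"4-(4-(2,2,2-trifluoroacetoxy)phenyl)-2-butanone",TRUE,TRUE,TRUE
ML,4-(4-formyloxyphenyl)-2-butanone,TRUE,TRUE,TRUE
AA,4-(4-methoxyphenyl)-2-butanone,FALSE,TRUE,TRUE
TMSRK,4-(4-((trimethylsilyl)oxy)phenyl)-2-butanone,FALSE,TRUE,TRUE
PRK,4-(4-propionyloxyphenyl)-2-butanone,TRUE,TRUE,TRUE
MAPP,methyl 3-(4-acetoxyphenyl)propionate,TRUE,FALSE,TRUE
RK,4-(4-hydroxyphenyl)-2-butanone,FALSE,TRUE,FALSE
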