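regulator,target,sign,evidence,in_initial_model,printed_regulator,printed_target
IND,ALC,activation,well_supported,TRUE,IND,ALC
SHP,ALC,activation,well_supported,TRUE,SHP1/2,ALC
MIR172,AP2,repression,well_supported,TRUE,miR172,AP2
AP2,MIR172,repression,well_supported,TRUE,AP2,ARF6/8
AP2,AS,repression,well_supported,TRUE,AP2,AS1/2
AP2,BP,repression,well_supported,FALSE,AP2,BP
AS,BP,repression,well_supported,TRUE,AS1/2,BP
SHP,IND,activation,well_supported,TRUE,SHP1/2,IND
BP,RPL,activation,well_supported,TRUE,BP,RPL
JFY,BP,repression,well_supported,TRUE,JAG/FIL/YAB3,BP
NTT,BP,activation,well_supported,FALSE,NTT,BP
BP,JFY,repression,well_supported,TRUE,BP,JAG/FIL/YAB3
FUL,FUL,activation,well_supported,FALSE,FUL,FUL
ALC,IND,repression,well_supported,FALSE,ALC,IND
AP2,IND,repression,well_supported,TRUE,AP2,IND
FUL,IND,repression,well_supported,TRUE,FUL,IND
FUL,MIR172,activation,well_supported,TRUE,FUL (+ARF6/8),miR172
AP2,RPL,repression,well_supported,TRUE,AP2,RPL
JFY,RPL,repression,well_supported,TRUE,JAG/FIL/YAB3,RPL
AP2,SHP,repression,well_supported,TRUE,AP2,SHP1/2
FUL,SHP,repression,well_supported,TRUE,FUL,SHP1/2
JFY,SHP,activation,well_supported,TRUE,JAG/FIL/YAB3,SHP1/2
FUL,ALC,repression,well_supported,TRUE,FUL,ALC
AP2,AP2,repression,well_supported,FALSE,AP2,AP2
FUL,AP2,repression,well_supported,FALSE,FUL,AP2
AS,JFY,repression,well_supported,FALSE,AS1/2,JAG/FIL/YAB3
JFY,FUL,activation,well_supported,TRUE,JAG/FIL/YAB3,FUL
NTT,JFY,repression,well_supported,FALSE,NTT,JAG/FIL/YAB3
AP2,MIR172,repression,well_supported,FALSE,AP2,miR172
NTT,NTT,activation,well_supported,FALSE,NTT,NTT
FUL,SPT,repression,well_supported,FALSE,FUL,SPT
IND,SPT,activation,well_supported,FALSE,IND,SPT
SHP,SPT,activation,well_supported,FALSE,SHP1/2,SPT
RPL,JFY,repression,suggested,TRUE,RPL,FIL
AS,FUL,activation,suggested,TRUE,AS1/2,FUL
BP,BP,activation,suggested,FALSE,BP,BP
SHP,AS,repression,suggested,FALSE,SHP1/2,AS1/2
IND,SHP,NA,ppi,FALSE,IND,SHP1/2
BP,AP2,NA,ppi,FALSE,BP,AP2
JFY,AP2,NA,ppi,FALSE,FIL,AP2
NTT,AS,NA,ppi,FALSE,NTT,AS1/2
RPL,BP,NA,ppi,FALSE,RPL,BP
SHP,BP,NA,ppi,FALSE,SHP1/2,BP
AP2,JFY,NA,ppi,FALSE,AP2,FIL
SHP,FUL,NA,ppi,FALSE,SHP1/2,FUL
RPL,IND,NA,ppi,FALSE,RPL,IND
JFY,JFY,NA,ppi,FALSE,JAG/YAB3,JAG/YAB3
NTT,FUL,NA,ppi,FALSE,NTT,FUL
NTT,RPL,NA,ppi,FALSE,NTT,RPL
NTT,SHP,NA,ppi,FALSE,NTT,SHP1/2
BP,SHP,NA,ppi,FALSE,BP,SHP1/2
NTT,FUL,repression,hypothetical,FALSE,NTT,FUL
NTT,SHP,activation,hypothetical,FALSE,NTT,SHP1/2
IND,FUL,repression,hypothetical,FALSE,IND,FUL
NTT,ALC,activation,hypothetical,FALSE,NTT,ALC
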