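node,V,LL,SL,R,VM
FUL,1,0,0,0,0
SHP,0,1,1,0,1
IND,0,1,1,0,1
ALC,0,0,1,0,1
SPT,NA,NA,NA,NA,NA
RPL,0,0,0,1,0
BP,0,0,0,1,0
JFY,1,1,1,0,1
AS,1,NA,NA,0,NA
AP2,NA,NA,NA,NA,NA
MIR172,NA,NA,NA,NA,NA
NTT,0,0,1,1,NA
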