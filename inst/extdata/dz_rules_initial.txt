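# Literature-compiled dehiscence-zone network (11 nodes, no NTT): only the
# experimentally validated interactions flagged for the first model version.
targets, factors
FUL, JFY & AS
SHP, JFY & !FUL
IND, SHP & !FUL
ALC, IND & SHP & !FUL
SPT, (IND | SHP) & !FUL
RPL, BP & !JFY
BP, !JFY & !AS
JFY, !BP & !RPL
AS, !AP2
AP2, !MIR172
MIR172, FUL & !AP2
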