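# Variant of the extended network restoring the reported quantitative
# ALC/SPT negative feedback on IND, which the default model leaves out:
# with it, the separation-layer state is no longer a fixed point and a
# cyclic attractor appears in its place.
targets, factors
FUL, JFY & !NTT & !IND
SHP, JFY & (NTT | !FUL)
IND, SHP & !FUL & !(ALC & SPT)
ALC, IND & SHP & NTT & !FUL
SPT, (IND | SHP) & !FUL
RPL, BP & !JFY
BP, NTT & !JFY & !AS
JFY, !RPL
AS, !SHP & !AP2
AP2, !FUL & !MIR172
MIR172, FUL & !AP2
NTT, NTT
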