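# Extended dehiscence-zone network (12 nodes): adds NTT and hypothetical
# interactions to the literature-compiled model. Reconstructed transcription;
# see the package vignette for provenance and the documented variant set.
targets, factors
FUL, JFY & !NTT & !IND
SHP, JFY & (NTT | !FUL)
IND, SHP & !FUL
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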