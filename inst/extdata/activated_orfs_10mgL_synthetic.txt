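HSP104
HSP42
SSE2
SSA4
SSA3
HSP78
ATM1
BPT1
QDR2
TPO1
AQR1
YRM1
GLK1
TRX2
SNQ2
SLN1
MSB2
ATF2
SOD1
CTT1
OGG1
RAD51
HOG1
GSH1
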