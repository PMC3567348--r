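GO:0051082	Unfolded protein binding	HSP104	HSP42	SSE2	SSA4	SSA3	HSP26	TIR1
GO:0055085	Transmembrane transport	ATM1	BPT1	QDR2	TPO1	AQR1	YRM1	HSP78	SSA4	SSA3	PDR5	YCF1	FLR1	ATR1	QDR3
GO:0006457	Protein folding	HSP104	HSP78	HSP42	SSE2	SSA4	SSA3	HSP26
GO:0006810	Transport	GLK1	TRX2	ATM1	SNQ2	BPT1	QDR2	TPO1	AQR1	YRM1	HSP78	SSA4	SSA3	PDR5	YCF1	FLR1	ATR1	QDR3	PDR1	PDR3	YRR1	BSD2	YHB1	TPS1	NTH1	GPD1	COX17	COR1	CYC7	ISM1	CCP1
GO:0042026	Protein refolding	HSP104	HSP78	SSE2
GO:0065002	Intracellular protein transmembrane transport	HSP78	SSA4	SSA3
GO:0051234	Establishment of localization	GLK1	TRX2	ATM1	SNQ2	BPT1	QDR2	TPO1	AQR1	YRM1	HSP78	SSA4	SSA3	PDR5	YCF1	FLR1	ATR1	QDR3	PDR1	PDR3	YRR1	BSD2	YHB1	TPS1	NTH1	GPD1	COX17	COR1	CYC7	ISM1	CCP1	TIP1	BFR2	PUN1
GO:0016021	Integral to membrane	SLN1	MSB2	ATM1	SNQ2	BPT1	QDR2	TPO1	AQR1	ATF2	PDR5	YCF1	FLR1	ATR1	QDR3	PUN1	TIR1	TIP1	IRE1	UTH1	BSD2
GO:0031224	Intrinsic to membrane	SLN1	MSB2	ATM1	SNQ2	BPT1	QDR2	TPO1	AQR1	ATF2	PDR5	YCF1	FLR1	ATR1	QDR3	PUN1	TIR1	TIP1	IRE1	UTH1	BSD2	YHB1	HSP12
GO:0007010	Cytoskeleton organization	CDC48	HSP42
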