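progenitor_synthetic	synthetic stand-in for the 77-gene ancient-essential progenitor signature	MCM6	PSMD4	HSPA9	POLA1	MCM7	CCT3	SNRPD1	CDC5L	PSMD14	SNRPE	POLE2	PSMC6	EIF3B	CDC45	CCT8	RPS3	PSMB7	RPS6	PSMD3	HSPD1	CDC20	PSMA7	MCM5	RFC3	EIF4A3	RFC5	CCT2	MCM4	POLA2	PRPF8	PCNA	PSMA1	SF3B1	PSMB2	PSMC1	RPL5	PSMB5	MCM3	PSMD7	POLE	PSMB4	PSMA4	PSMA2	POLD1	PSMB6	MCM2	RPL3	PSMA5	PSMB1	PSMC2	CCT5	NUP93	CCT7	PSMC4	CDC27	PSMC5	POLD2	RAN	PSMC3	PSMD1	PSMB3	PSMD12	XPO1	PSMD2	CCT6A	EIF2S1	RUVBL2	PRIM1	CCT4	PSMA3	SMC2	RFC4	RUVBL1	PSMD6	PSMA6	RFC2	PSMD11
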