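symbol	phyletic_age	essential
MCM6	Eukaryota	TRUE
PSMD4	Eukaryota	TRUE
POU5F1	Chordata	TRUE
HSPA9	cellular organisms	TRUE
POLA1	cellular organisms	TRUE
PAX6	Metazoa	FALSE
MCM7	Eukaryota	TRUE
CCT3	Eukaryota	TRUE
GSTP1	cellular organisms	FALSE
SNRPD1	Eukaryota	TRUE
CDC5L	Eukaryota	TRUE
PSMD14	Eukaryota	TRUE
RB1	Metazoa	TRUE
SNRPE	Eukaryota	TRUE
COL1A1	Metazoa	FALSE
POLE2	Eukaryota	TRUE
PSMC6	Eukaryota	TRUE
EIF3B	Eukaryota	TRUE
CDC45	Eukaryota	TRUE
CCT8	Eukaryota	TRUE
MYH7	Metazoa	FALSE
RPS3	cellular organisms	TRUE
DMD	Metazoa	FALSE
PSMB7	cellular organisms	TRUE
RPS6	cellular organisms	TRUE
GPX1	cellular organisms	FALSE
PSMD3	Eukaryota	TRUE
APOE	Mammalia	FALSE
HSPD1	cellular organisms	TRUE
GATA4	Metazoa	TRUE
CDC20	Eukaryota	TRUE
PSMA7	cellular organisms	TRUE
MCM5	Eukaryota	TRUE
RFC3	cellular organisms	TRUE
EIF4A3	Eukaryota	TRUE
RFC5	cellular organisms	TRUE
CCT2	Eukaryota	TRUE
MCM4	Eukaryota	TRUE
POLA2	Eukaryota	TRUE
PRPF8	Eukaryota	TRUE
PCNA	cellular organisms	TRUE
PSMA1	cellular organisms	TRUE
SF3B1	Eukaryota	TRUE
PSMB2	cellular organisms	TRUE
TXN	cellular organisms	FALSE
IDH2	Eukaryota	FALSE
PSMC1	Eukaryota	TRUE
RPL5	cellular organisms	TRUE
MYC	Metazoa	TRUE
NANOG	Mammalia	FALSE
PSMB5	cellular organisms	TRUE
MCM3	Eukaryota	TRUE
PSMD7	Eukaryota	TRUE
POLE	cellular organisms	TRUE
HBB	Chordata	FALSE
PSMB4	cellular organisms	TRUE
PSMA4	cellular organisms	TRUE
PSMA2	cellular organisms	TRUE
POLD1	cellular organisms	TRUE
VEGFA	Chordata	FALSE
ALDH2	Eukaryota	FALSE
EGFR	Metazoa	FALSE
CDKN2A	Chordata	FALSE
PSMB6	cellular organisms	TRUE
SOD2	Eukaryota	FALSE
BRCA2	Chordata	TRUE
TNNT2	Chordata	TRUE
CFTR	Chordata	FALSE
TP53	Metazoa	TRUE
MCM2	Eukaryota	TRUE
RPL3	cellular organisms	TRUE
PSMA5	cellular organisms	TRUE
PSMB1	cellular organisms	TRUE
CAT	cellular organisms	FALSE
INS	Chordata	FALSE
PSMC2	Eukaryota	TRUE
CCT5	Eukaryota	TRUE
OPN1LW	Mammalia	FALSE
NUP93	Eukaryota	TRUE
AMELX	Mammalia	FALSE
CCT7	Eukaryota	TRUE
PSMC4	Eukaryota	TRUE
CDC27	Eukaryota	TRUE
PSMC5	Eukaryota	TRUE
POLD2	Eukaryota	TRUE
RAN	Eukaryota	TRUE
PSMC3	Eukaryota	TRUE
PSMD1	Eukaryota	TRUE
PSMB3	cellular organisms	TRUE
PSMD12	Eukaryota	TRUE
TTN	Chordata	FALSE
PRDX1	Eukaryota	FALSE
XPO1	Eukaryota	TRUE
PSMD2	Eukaryota	TRUE
CCT6A	Eukaryota	TRUE
EIF2S1	cellular organisms	TRUE
RUVBL2	Eukaryota	TRUE
PRIM1	cellular organisms	TRUE
CCT4	Eukaryota	TRUE
ALB	Chordata	FALSE
PSMA3	cellular organisms	TRUE
SOX2	Metazoa	TRUE
BRCA1	Chordata	TRUE
SMC2	Eukaryota	TRUE
RFC4	cellular organisms	TRUE
ACTN2	Fungi/Metazoa group	FALSE
FOXP2	Mammalia	FALSE
RUVBL1	Eukaryota	TRUE
KRT14	Chordata	FALSE
PSMD6	Eukaryota	TRUE
PSMA6	cellular organisms	TRUE
RFC2	cellular organisms	TRUE
PTEN	Metazoa	TRUE
KRAS	Eukaryota	FALSE
PSMD11	Eukaryota	TRUE
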