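# Curated 45-gene pluripotency network (synthetic transcription; see
# pluripotency_edges_provenance.tsv for edge-by-edge provenance).
# 45 nodes, 65 non-self edges (4 with undefined sign) and 4 positive
# auto-regulatory loops: 69 interactions in total.
source	sign	target
SALL4	+	POU5F1
L1TD1	+	POU5F1
POU5F1	+	POU5F1
POU5F1	+	SOX2
NANOG	+	SOX2
GATA6	-	SOX2
POU5F1	+	NANOG
SOX2	+	NANOG
GATA6	-	NANOG
POU5F1	+	SALL4
NANOG	+	SALL4
POU5F1	+	L1TD1
NANOG	+	L1TD1
L1TD1	+	KLF4
NANOG	?	KLF4
POU5F1	+	UTF1
SOX2	+	UTF1
POU5F1	+	ZFP42
NANOG	+	ZFP42
NANOG	+	HESX1
POU5F1	+	FOXD3
NANOG	+	PRDM14
POU5F1	+	DPPA4
POU5F1	+	GDF3
NANOG	+	TDGF1
POU5F1	+	LIN28A
MYC	+	LIN28A
POU5F1	+	KLF2
STAT3	+	KLF2
FGF2	+	MYC
GSK3B	-	MYC
LIFR	+	STAT3
GATA6	-	STAT3
STAT3	+	STAT3
LIF	+	LIFR
NANOG	+	LIF
POU5F1	+	INHBA
NANOG	-	GATA6
BMP4	+	GATA6
POU5F1	-	BMP4
MSX1	+	BMP4
POU5F1	-	MSX1
BMP4	+	MSX1
GATA3	+	MSX1
POU5F1	-	CDX2
POU5F1	-	TBXT
POU5F1	-	EOMES
NANOG	-	GATA3
BMP4	+	GATA3
BMP4	+	HAND1
GATA6	+	GATA4
GATA6	+	SOX17
GATA4	+	HNF4A
GATA4	+	AFP
GATA6	+	LHX1
SOX2	-	PAX6
PAX6	+	NEUROG1
REST	-	NEUROG1
PAX6	+	NES
REST	-	NES
TBXT	+	WNT5A
STAT3	+	FGF2
FGF2	+	FGF2
STAT3	+	REST
REST	+	REST
WNT5A	-	GSK3B
NANOG	?	TBX3
POU5F1	?	TBX3
SOX2	?	TBX3
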