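# Edge-by-edge provenance of the packaged pluripotency fixture.
# The full curated edge list of the original 45-node network is published
# only as a figure and supplementary file, so this fixture is a SYNTHETIC
# transcription: `named` edges implement interactions named in the primary
# literature on the human pluripotency circuit; `constraint` rows encode
# documented absences or structural facts (counts, loop placement); `infill`
# edges are literature-plausible synthetic wiring added to reach the
# published network size while reproducing the documented knockdown
# behaviour of the core circuit.
source	sign	target	network	origin
NANOG	-	KLF4	inferred	named: NANOG represses KLF4 (learned interaction)
NANOG	+	TBX3	inferred	named: TBX3 activated by NANOG, POU5F1 and SOX2
POU5F1	+	TBX3	inferred	named: TBX3 activated by NANOG, POU5F1 and SOX2
SOX2	+	TBX3	inferred	named: TBX3 activated by NANOG, POU5F1 and SOX2
FGF2	+	FGFR2	inferred	named: FGFR2 is activated by FGF2
FGFR2	-	TCF3	inferred	named: FGFR2 inhibits TCF3
FGFR2	-	NOG	inferred	named: FGFR2 inhibits NOG
FGFR2	-	BMP4	inferred	named: FGFR2 inhibits BMP4
MYC	-	MYC	inferred	named: c-MYC negative auto-regulatory loop
NANOG	?	KLF4	curated	constraint: KLF4 regulation unspecified in the curated network
NANOG	?	TBX3	curated	constraint: TBX3 regulation unspecified in the curated network
POU5F1	?	TBX3	curated	constraint: TBX3 regulation unspecified in the curated network
SOX2	?	TBX3	curated	constraint: TBX3 regulation unspecified in the curated network
POU5F1	+	POU5F1	curated	constraint: one of 4 positive auto-regulatory loops (loop genes not published; placement synthetic)
STAT3	+	STAT3	curated	constraint: one of 4 positive auto-regulatory loops (placement synthetic)
FGF2	+	FGF2	curated	constraint: one of 4 positive auto-regulatory loops (placement synthetic)
REST	+	REST	curated	constraint: one of 4 positive auto-regulatory loops (placement synthetic)
L1TD1	+	POU5F1	curated	named: L1TD1 can activate POU5F1
L1TD1	+	KLF4	curated	named: L1TD1 can activate KLF4
POU5F1	+	SOX2	curated	infill: core-circuit cross-activation (no NANOG->POU5F1 edge, per documented NANOG-knockdown insensitivity of POU5F1)
NANOG	+	SOX2	curated	infill: core-circuit cross-activation
POU5F1	+	NANOG	curated	infill: core-circuit cross-activation (POU5F1-SOX2 dimer AND-joined in logic)
SOX2	+	NANOG	curated	infill: core-circuit cross-activation
SALL4	+	POU5F1	curated	infill: pluripotency TF mutual support
POU5F1	+	SALL4	curated	infill
NANOG	+	SALL4	curated	infill
POU5F1	+	L1TD1	curated	infill: core circuit drives L1TD1
NANOG	+	L1TD1	curated	infill
POU5F1	+	UTF1	curated	infill: UTF1 strongly regulated by the core circuit
SOX2	+	UTF1	curated	infill
POU5F1	+	ZFP42	curated	infill
NANOG	+	ZFP42	curated	infill
NANOG	+	HESX1	curated	infill: HESX1 shuts down with the core circuit
POU5F1	+	FOXD3	curated	infill
NANOG	+	PRDM14	curated	infill
POU5F1	+	DPPA4	curated	infill
POU5F1	+	GDF3	curated	infill
NANOG	+	TDGF1	curated	infill
POU5F1	+	LIN28A	curated	infill
MYC	+	LIN28A	curated	infill
POU5F1	+	KLF2	curated	infill
STAT3	+	KLF2	curated	infill
FGF2	+	MYC	curated	infill: growth-factor signalling drives MYC
GSK3B	-	MYC	curated	infill: GSK3B destabilizes MYC
LIFR	+	STAT3	curated	infill: LIF/LIFR/STAT3 axis
LIF	+	LIFR	curated	infill
NANOG	+	LIF	curated	infill: LIF and LIFR fall with the core circuit
GATA6	-	STAT3	curated	infill: endoderm programme antagonizes the naive axis
GATA6	-	SOX2	curated	infill
GATA6	-	NANOG	curated	infill
NANOG	-	GATA6	curated	infill: core circuit represses endoderm drivers
BMP4	+	GATA6	curated	infill
POU5F1	-	BMP4	curated	infill: core circuit holds BMP signalling off
MSX1	+	BMP4	curated	infill: BMP4-MSX1 mutual reinforcement
POU5F1	-	MSX1	curated	infill
BMP4	+	MSX1	curated	infill
GATA3	+	MSX1	curated	infill: BMP4/GATA3/MSX1 reinforcing triangle
POU5F1	-	CDX2	curated	infill: trophectoderm programme repressed by POU5F1
POU5F1	-	TBXT	curated	infill: mesodermal genes rise on POU5F1 loss
POU5F1	-	EOMES	curated	infill
NANOG	-	GATA3	curated	infill
BMP4	+	GATA3	curated	infill
BMP4	+	HAND1	curated	infill
GATA6	+	GATA4	curated	infill: endoderm cascade
GATA6	+	SOX17	curated	infill
GATA4	+	HNF4A	curated	infill
GATA4	+	AFP	curated	infill
GATA6	+	LHX1	curated	infill
SOX2	-	PAX6	curated	infill: neuroectoderm held off in the pluripotent state
PAX6	+	NEUROG1	curated	infill
REST	-	NEUROG1	curated	named: REST represses neuronal-specific genes
PAX6	+	NES	curated	infill
REST	-	NES	curated	infill
TBXT	+	WNT5A	curated	infill: mesodermal WNT branch
WNT5A	-	GSK3B	curated	infill: WNT signalling inactivates GSK3B
STAT3	+	FGF2	curated	infill: autocrine growth-factor loop sustained by STAT3
STAT3	+	REST	curated	infill
POU5F1	+	INHBA	curated	infill: TGF-beta family member INHBA falls with POU5F1
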