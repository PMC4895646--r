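# Illustrative EGFR/TNFR/DNA-damage signaling toy network (synthetic;
# hand-curated for examples, not a reconstruction of any published map).
# Columns: source  sign  weight  target
#! nodes: EGFR TNFR DNADamage PI3K RAS ERK AKT JNK p53 PUMA Casp8 Proliferation Apoptosis
#! inputs: EGFR TNFR DNADamage
EGFR	+	0.7	PI3K
EGFR	+	0.7	RAS
RAS	+	0.7	ERK
PI3K	+	0.7	AKT
AKT	-	0.8	p53
AKT	-	0.8	Casp8
TNFR	+	0.7	JNK
JNK	+	0.7	Casp8
DNADamage	+	0.7	p53
p53	+	0.7	PUMA
PUMA	+	0.7	Apoptosis
Casp8	+	0.7	Apoptosis
ERK	+	0.7	Proliferation
p53	-	0.8	Proliferation
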