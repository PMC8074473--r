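parent	child
PKC	RAF
PKC	MEK
PKC	JNK
PKC	P38
PKC	PKA
PKA	RAF
PKA	MEK
PKA	ERK
PKA	AKT
PKA	JNK
PKA	P38
RAF	MEK
MEK	ERK
ERK	AKT
PLCG	PIP2
PLCG	PKC
PIP3	PLCG
PIP3	PIP2
PIP3	AKT
PIP2	PKC
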