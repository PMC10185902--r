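name	haplogroup	position	ancestral	derived
M175	O	2950000	ATTCTC	A
M111	O1b1a1a1a1a1	2950100	AC	A
A15721	O1b1a1a1a1a1a1a1a	2950200	AG	A
M121	O2a1a1a1a1	2950300	AT	A
FGC12511	O2a1b1a	2950400	A	AT
M134	O2a2b1	2950500	AG	A
M117	O2a2b1a1	2950600	ACT	A
M133	O2a2b1a1a	2950700	A	AC
M333	O2a4	2950800	AGA	A
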