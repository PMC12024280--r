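tank	group	families	stocked	harvested
A1	A	10	200	167
A2	A	11	220	183
A3	A	11	220	183
B1	B	10	200	157
B2	B	11	220	169
B3	B	10	200	151
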