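parameter	trait_x	trait_y	estimate	se
h2_stgm	MY	NA	0.160	0.048
h2_stgm	MW	NA	0.197	0.050
h2_stgm	BW	NA	0.158	0.046
h2_stgm	BL	NA	0.133	0.044
h2_stgm	AL	NA	0.101	0.039
rg	MY	MW	0.783	0.133
rg	MY	BW	0.636	0.200
rg	MY	BL	0.605	0.213
rg	MY	AL	0.286	0.248
rg	MW	BW	0.978	0.013
rg	MW	BL	0.915	0.040
rg	MW	AL	0.735	0.106
rg	BW	BL	0.935	0.029
rg	BW	AL	0.811	0.089
rg	BL	AL	0.924	0.047
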