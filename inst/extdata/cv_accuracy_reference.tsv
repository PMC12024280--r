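target	model	strategy	accuracy	bias
MY	STGM	CV2	0.187	0.972
MY	MY-MW	CV1	0.297	1.326
MY	MY-BW	CV1	0.204	1.018
MY	MY-BL	CV1	0.197	0.973
MY	MY-AL	CV1	0.196	1.031
MY	MY-MW	CV2	0.203	1.012
MY	MY-BW	CV2	0.199	1.002
MY	MY-BL	CV2	0.195	0.985
MY	MY-AL	CV2	0.189	1.046
MW	STGM	CV2	0.254	1.021
MW	MW-MY	CV1	0.347	1.268
MW	MW-BW	CV1	0.605	2.093
MW	MW-BL	CV1	0.557	1.983
MW	MW-AL	CV1	0.466	1.710
MW	MW-MY	CV2	0.256	1.006
MW	MW-BW	CV2	0.261	1.032
MW	MW-BL	CV2	0.265	1.046
MW	MW-AL	CV2	0.252	0.984
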