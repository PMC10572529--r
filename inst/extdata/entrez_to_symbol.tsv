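hsa:5925	RB1
hsa:1869	E2F1
hsa:1870	E2F2
hsa:1871	E2F3
hsa:595	CCND1
hsa:1019	CDK4
hsa:1021	CDK6
hsa:1026	CDKN1A
hsa:1029	CDKN2A
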