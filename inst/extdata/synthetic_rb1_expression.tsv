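gene	P01	P02	P03	P04
RB1	9.1	8.4	7.9	9.5
CCND1	10.0	9.8	9.2	10.4
E2F1	8.0	8.8	7.1	8.2
E2F2	7.6	8.1	6.9	8.0
E2F3	7.9	7.7	7.4	8.3
CDK4	8.2	7.9	7.2	8.6
CDK6	7.8	8.0	7.0	8.1
CDKN1A	1.2	0.8	NA	1.5
CDKN2A	0.0	0.4	0.3	0.2
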