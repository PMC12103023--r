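source	target	sign
S0	S1	1
S0	S2	1
S0	S3	1
S0	S4	1
S0	S5	1
S1	S10	1
S1	S6	1
S1	S7	1
S1	S8	1
S11	S2	1
S12	S2	1
S13	S2	1
S14	S2	1
S16	S3	1
S17	S3	1
S18	S3	1
S19	S3	1
S20	S3	1
S21	S4	1
S22	S4	1
S23	S4	1
S24	S4	1
S25	S4	1
S26	S5	1
S27	S5	1
S28	S5	1
S29	S5	1
S30	S5	1
S1	S9	-1
S15	S2	-1
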