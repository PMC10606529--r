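chrT1	46990	47100	E1	0	+
chrT2	6990	7100	E2	0	-
chrT2	9900	10001	E3	0	+
chrT3	36990	37100	E4	0	+
chrT3	80000	80200	E5	0	+
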