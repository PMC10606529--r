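chrT1	1000	7000	A01	0	+
chrT1	11000	17000	A02	0	+
chrT1	21000	27000	A03	0	+
chrT1	31000	37000	A04	0	+
chrT1	41000	47000	A05	0	+
chrT1	51000	57000	A06	0	+
chrT1	61000	67000	A07	0	+
chrT1	71000	77000	A08	0	+
chrT1	81000	87000	A09	0	+
chrT1	91000	97000	A10	0	+
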