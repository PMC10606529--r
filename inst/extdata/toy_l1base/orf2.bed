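chrT3	1000	7000	O01	0	+
chrT3	11000	17000	O02	0	+
chrT3	21000	27000	O03	0	+
chrT3	31000	37000	O04	0	+
chrT3	41000	47000	O05	0	+
chrT3	51000	57000	O06	0	+
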