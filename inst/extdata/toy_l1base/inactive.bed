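chrT2	1000	7000	I01	0	+
chrT2	10000	16000	I02	0	-
chrT1	16999	18000	I03	0	+
chrT2	20000	26000	I04	0	+
chrT2	28000	34000	I05	0	+
chrT2	36000	42000	I06	0	+
chrT2	44000	50000	I07	0	+
chrT2	52000	58000	I08	0	+
chrT2	60000	66000	I09	0	+
chrT1	66500	68000	I10	0	-
chrT2	68000	74000	I11	0	+
chrT2	76000	82000	I12	0	+
chrT2	84000	90000	I13	0	+
chrT2	92000	98000	I14	0	+
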