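mirna	transcript	gene	reads	energy
miR-01	GENE1.1	GENE1	23	-14.42
miR-01	GENE2.1	GENE2	28	-16.79
miR-02	GENE1.1	GENE1	7	-15.43
miR-02	GENE2.1	GENE2	9	-19.07
miR-03	GENE2.1	GENE2	6	-14.72
miR-03	GENE3.1	GENE3	16	-21.7
miR-04	GENE2.1	GENE2	30	-18.65
miR-04	GENE3.1	GENE3	18	-21.27
miR-05	GENE3.1	GENE3	30	-21.53
miR-05	GENE4.1	GENE4	39	-21.01
miR-06	GENE3.1	GENE3	17	-16.95
miR-06	GENE4.1	GENE4	40	-14.42
miR-07	GENE4.1	GENE4	39	-17.32
miR-07	GENE5.1	GENE5	6	-14.19
miR-08	GENE4.1	GENE4	5	-17.55
miR-08	GENE5.1	GENE5	11	-19.68
miR-09	GENE5.1	GENE5	12	-17.67
miR-09	GENE6.1	GENE6	39	-19.53
miR-10	GENE5.1	GENE5	14	-21.18
miR-10	GENE6.1	GENE6	39	-16.89
miR-11	GENE1.1	GENE1	26	-21.22
miR-12	GENE2.1	GENE2	7	-17.49
miR-13	GENE4.1	GENE4	16	-18.03
miR-14	GENE5.1	GENE5	37	-18.58
miR-15	GENE6.1	GENE6	23	-18.28
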