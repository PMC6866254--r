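# Atlantic salmon IGH constant (C) genes and the D and J genes of their
# clusters, one row per allele functionality. Genes whose alleles differ
# (F, ORF) appear as two rows. Printed symbol slips (IGHJIT4, IGHJIT5,
# IGHJID) are kept verbatim; loaders normalize them.
name	species	locus_id	chromosome	start	stop	polarity	subgroup	allele	functionality
IGHT1	Salsal	A	ssa06	100	1500	same		01	P
IGHD1T2	Salsal	A	ssa06	2000	2020	same		01	F
IGHD2T2	Salsal	A	ssa06	2100	2120	same		01	F
IGHJ1T2	Salsal	A	ssa06	2500	2550	same		01	F
IGHJ2T2	Salsal	A	ssa06	2600	2650	same		01	F
IGHT2	Salsal	A	ssa06	3000	4500	same		01	P
IGHJ1T3	Salsal	A	ssa06	5000	5050	same		01	F
IGHJ2T3	Salsal	A	ssa06	5100	5150	same		01	F
IGHT3	Salsal	A	ssa06	5500	7000	same		01	P
IGHD1T4	Salsal	A	ssa06	7500	7520	same		01	F
IGHD2T4	Salsal	A	ssa06	7600	7620	same		01	F
IGHD3T4	Salsal	A	ssa06	7700	7720	same		01	F
IGHD4T4	Salsal	A	ssa06	7800	7820	same		01	F
IGHD5T4	Salsal	A	ssa06	7900	7920	same		01	F
IGHJIT4	Salsal	A	ssa06	8000	8050	same		01	F
IGHJ2T4	Salsal	A	ssa06	8100	8150	same		01	F
IGHT4	Salsal	A	ssa06	8500	10000	same		01	F
IGHD1T5	Salsal	A	ssa06	10500	10520	same		01	F
IGHJIT5	Salsal	A	ssa06	10600	10650	same		01	P
IGHJ2T5	Salsal	A	ssa06	10700	10750	same		01	F
IGHT5	Salsal	A	ssa06	11000	12500	same		01	P
IGHD1	Salsal	A	ssa06	13000	13020	same		01	F
IGHD2	Salsal	A	ssa06	13100	13120	same		01	F
IGHD3	Salsal	A	ssa06	13200	13220	same		01	F
IGHD4	Salsal	A	ssa06	13300	13320	same		01	F
IGHD5	Salsal	A	ssa06	13400	13420	same		01	F
IGHD6	Salsal	A	ssa06	13500	13520	same		01	F
IGHD7	Salsal	A	ssa06	13600	13620	same		01	F
IGHD8	Salsal	A	ssa06	13700	13720	same		01	F
IGHD9	Salsal	A	ssa06	13800	13820	same		01	F
IGHJ1	Salsal	A	ssa06	14000	14050	same		01	F
IGHJ2	Salsal	A	ssa06	14100	14150	same		01	ORF
IGHJ3	Salsal	A	ssa06	14200	14250	same		01	F
IGHJ4	Salsal	A	ssa06	14300	14350	same		01	F
IGHJ5	Salsal	A	ssa06	14400	14450	same		01	F
IGHJ5	Salsal	A	ssa06	14400	14450	same		02	ORF
IGHM	Salsal	A	ssa06	15000	17000	same		01	F
IGHD	Salsal	A	ssa06	17500	21000	same		01	F
IGHJ1T1D	Salsal	B	ssa03	100	150	same		01	P
IGHT1D	Salsal	B	ssa03	500	2000	same		01	P
IGHD1T2D	Salsal	B	ssa03	2500	2520	same		01	F
IGHD2T2D	Salsal	B	ssa03	2600	2620	same		01	F
IGHJ1T2D	Salsal	B	ssa03	2700	2750	same		01	F
IGHJ2T2D	Salsal	B	ssa03	2800	2850	same		01	F
IGHT2D	Salsal	B	ssa03	3200	4700	same		01	F
IGHT3D	Salsal	B	ssa03	5000	6500	same		01	P
IGHD1T3D	Salsal	B	ssa03	6600	6620	same		01	F
IGHD2T3D	Salsal	B	ssa03	6700	6720	same		01	F
IGHD3T3D	Salsal	B	ssa03	6800	6820	same		01	F
IGHD1D	Salsal	B	ssa03	7000	7020	same		01	F
IGHD2D	Salsal	B	ssa03	7100	7120	same		01	F
IGHD3D	Salsal	B	ssa03	7200	7220	same		01	F
IGHD4D	Salsal	B	ssa03	7300	7320	same		01	F
IGHD5D	Salsal	B	ssa03	7400	7420	same		01	F
IGHD6D	Salsal	B	ssa03	7500	7520	same		01	F
IGHJID	Salsal	B	ssa03	7600	7650	same		01	F
IGHJ2D	Salsal	B	ssa03	7700	7750	same		01	F
IGHJ3D	Salsal	B	ssa03	7800	7850	same		01	F
IGHJ4D	Salsal	B	ssa03	7900	7950	same		01	F
IGHJ5D	Salsal	B	ssa03	8000	8050	same		01	F
IGHJ5D	Salsal	B	ssa03	8000	8050	same		02	ORF
IGHMD	Salsal	B	ssa03	8500	10500	same		01	F
IGHDD	Salsal	B	ssa03	11000	14500	same		01	F
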