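# Rainbow trout IGH constant (C) genes and the D and J genes of their
# clusters, one row per allele functionality. The IGHMD functionality cell
# is blank in the source table (the mu/delta functionality on locus B is
# supported only by external evidence); it is preserved as unstated.
name	species	locus_id	chromosome	start	stop	polarity	subgroup	allele	functionality
IGHD1T1	Oncmyk	A	omy13	100	120	same		01	F
IGHD2T1	Oncmyk	A	omy13	200	220	same		01	F
IGHD3T1	Oncmyk	A	omy13	300	320	same		01	F
IGHJ1T1	Oncmyk	A	omy13	400	450	same		01	F
IGHJ2T1	Oncmyk	A	omy13	500	550	same		01	F
IGHT1	Oncmyk	A	omy13	700	2200	same		01	P
IGHD1T2	Oncmyk	A	omy13	2500	2520	same		01	F
IGHD2T2	Oncmyk	A	omy13	2600	2620	same		01	F
IGHJ1T2	Oncmyk	A	omy13	2700	2750	same		01	F
IGHJ2T2	Oncmyk	A	omy13	2800	2850	same		01	F
IGHT2	Oncmyk	A	omy13	3200	4700	same		01	F
IGHD1	Oncmyk	A	omy13	5000	5020	same		01	F
IGHD2	Oncmyk	A	omy13	5100	5120	same		01	F
IGHD3	Oncmyk	A	omy13	5200	5220	same		01	F
IGHD4	Oncmyk	A	omy13	5300	5320	same		01	F
IGHD5	Oncmyk	A	omy13	5400	5420	same		01	F
IGHD6	Oncmyk	A	omy13	5500	5520	same		01	F
IGHJ1	Oncmyk	A	omy13	5600	5650	same		01	F
IGHJ2	Oncmyk	A	omy13	5700	5750	same		01	F
IGHJ3	Oncmyk	A	omy13	5800	5850	same		01	F
IGHJ4	Oncmyk	A	omy13	5900	5950	same		01	F
IGHJ5	Oncmyk	A	omy13	6000	6050	same		01	F
IGHJ6	Oncmyk	A	omy13	6100	6150	same		01	F
IGHM	Oncmyk	A	omy13	6500	8500	same		01	F
IGHD	Oncmyk	A	omy13	9000	12500	same		01	F
IGHD1T1D	Oncmyk	B	omy12	100	120	same		01	F
IGHD2T1D	Oncmyk	B	omy12	200	220	same		01	F
IGHD3T1D	Oncmyk	B	omy12	300	320	same		01	ORF
IGHD4T1D	Oncmyk	B	omy12	400	420	same		01	F
IGHJ1T1D	Oncmyk	B	omy12	500	550	same		01	F
IGHJ2T1D	Oncmyk	B	omy12	600	650	same		01	F
IGHT1D	Oncmyk	B	omy12	800	2300	same		01	F
IGHD1D	Oncmyk	B	omy12	2600	2620	same		01	F
IGHD2D	Oncmyk	B	omy12	2700	2720	same		01	F
IGHD3D	Oncmyk	B	omy12	2800	2820	same		01	F
IGHD4D	Oncmyk	B	omy12	2900	2920	same		01	F
IGHD5D	Oncmyk	B	omy12	3000	3020	same		01	F
IGHD6D	Oncmyk	B	omy12	3100	3120	same		01	F
IGHJ1D	Oncmyk	B	omy12	3200	3250	same		01	F
IGHJ2D	Oncmyk	B	omy12	3300	3350	same		01	F
IGHJ3D	Oncmyk	B	omy12	3400	3450	same		01	F
IGHJ4D	Oncmyk	B	omy12	3500	3550	same		01	F
IGHJ5D	Oncmyk	B	omy12	3600	3650	same		01	F
IGHJ6D	Oncmyk	B	omy12	3700	3750	same		01	F
IGHJ7D	Oncmyk	B	omy12	3800	3850	same		01	F
IGHMD	Oncmyk	B	omy12	4200	6200	same		01
IGHDD	Oncmyk	B	omy12	6700	10200	same		01	F
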