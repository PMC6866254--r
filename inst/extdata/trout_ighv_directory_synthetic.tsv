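# Rainbow trout IGHV reference-directory gene table (SYNTHETIC gene-level
# expansion). One row per allele (all *01). Counts per subgroup x locus x
# functionality reproduce the published directory composition; names,
# positions and coordinates are synthetic placeholders. Every pseudogene
# row is in-frame (out-of-frame pseudogenes never enter a directory).
name	species	locus_id	chromosome	start	stop	polarity	subgroup	allele	functionality	in_frame
IGHV1-1	Oncmyk	A	omy13	48004000	48004299	same	1	01	F	FALSE
IGHV1-2	Oncmyk	A	omy13	48008000	48008299	same	1	01	F	FALSE
IGHV1-3	Oncmyk	A	omy13	48012000	48012299	same	1	01	F	FALSE
IGHV1-4	Oncmyk	A	omy13	48016000	48016299	same	1	01	F	FALSE
IGHV1-5	Oncmyk	A	omy13	48020000	48020299	same	1	01	F	FALSE
IGHV1-6	Oncmyk	A	omy13	48024000	48024299	same	1	01	F	FALSE
IGHV1-7	Oncmyk	A	omy13	48028000	48028299	same	1	01	P	TRUE
IGHV1-8	Oncmyk	A	omy13	48032000	48032299	same	1	01	P	TRUE
IGHV1D-1	Oncmyk	B	omy12	81796000	81796299	same	1	01	F	FALSE
IGHV1D-2	Oncmyk	B	omy12	81792000	81792299	same	1	01	F	FALSE
IGHV1D-3	Oncmyk	B	omy12	81788000	81788299	same	1	01	F	FALSE
IGHV1D-4	Oncmyk	B	omy12	81784000	81784299	same	1	01	F	FALSE
IGHV1D-5	Oncmyk	B	omy12	81780000	81780299	same	1	01	F	FALSE
IGHV1D-6	Oncmyk	B	omy12	81776000	81776299	same	1	01	ORF	FALSE
IGHV1D-7	Oncmyk	B	omy12	81772000	81772299	same	1	01	ORF	FALSE
IGHV1D-8	Oncmyk	B	omy12	81768000	81768299	same	1	01	P	TRUE
IGHV1D-9	Oncmyk	B	omy12	81764000	81764299	same	1	01	P	TRUE
IGHV2-9	Oncmyk	A	omy13	48036000	48036299	same	2	01	F	FALSE
IGHV2-10	Oncmyk	A	omy13	48040000	48040299	same	2	01	F	FALSE
IGHV2-11	Oncmyk	A	omy13	48044000	48044299	same	2	01	P	TRUE
IGHV2D-10	Oncmyk	B	omy12	81760000	81760299	same	2	01	F	FALSE
IGHV2D-11	Oncmyk	B	omy12	81756000	81756299	same	2	01	F	FALSE
IGHV2D-12	Oncmyk	B	omy12	81752000	81752299	same	2	01	F	FALSE
IGHV2D-13	Oncmyk	B	omy12	81748000	81748299	same	2	01	P	TRUE
IGHV2D-14	Oncmyk	B	omy12	81744000	81744299	same	2	01	P	TRUE
IGHV3-12	Oncmyk	A	omy13	48048000	48048299	same	3	01	F	FALSE
IGHV3D-15	Oncmyk	B	omy12	81740000	81740299	same	3	01	ORF	FALSE
IGHV4-13	Oncmyk	A	omy13	48052000	48052299	same	4	01	P	TRUE
IGHV4D-16	Oncmyk	B	omy12	81736000	81736299	same	4	01	F	FALSE
IGHV4D-17	Oncmyk	B	omy12	81732000	81732299	same	4	01	F	FALSE
IGHV4D-18	Oncmyk	B	omy12	81728000	81728299	same	4	01	F	FALSE
IGHV4D-19	Oncmyk	B	omy12	81724000	81724299	same	4	01	F	FALSE
IGHV4D-20	Oncmyk	B	omy12	81720000	81720299	same	4	01	P	TRUE
IGHV4D-21	Oncmyk	B	omy12	81716000	81716299	same	4	01	P	TRUE
IGHV4D-22	Oncmyk	B	omy12	81712000	81712299	same	4	01	P	TRUE
IGHV4D-23	Oncmyk	B	omy12	81708000	81708299	same	4	01	P	TRUE
IGHV6-14	Oncmyk	A	omy13	48056000	48056299	same	6	01	F	FALSE
IGHV6-15	Oncmyk	A	omy13	48060000	48060299	same	6	01	F	FALSE
IGHV6-16	Oncmyk	A	omy13	48064000	48064299	same	6	01	ORF	FALSE
IGHV6D-24	Oncmyk	B	omy12	81704000	81704299	same	6	01	F	FALSE
IGHV6D-25	Oncmyk	B	omy12	81700000	81700299	same	6	01	F	FALSE
IGHV6D-26	Oncmyk	B	omy12	81696000	81696299	same	6	01	F	FALSE
IGHV6D-27	Oncmyk	B	omy12	81692000	81692299	same	6	01	P	TRUE
IGHV6D-28	Oncmyk	B	omy12	81688000	81688299	same	6	01	P	TRUE
IGHV7D-29	Oncmyk	B	omy12	81684000	81684299	same	7	01	ORF	FALSE
IGHV7D-30	Oncmyk	B	omy12	81680000	81680299	same	7	01	ORF	FALSE
IGHV7D-31	Oncmyk	B	omy12	81676000	81676299	same	7	01	ORF	FALSE
IGHV7D-32	Oncmyk	B	omy12	81672000	81672299	same	7	01	ORF	FALSE
IGHV8-17	Oncmyk	A	omy13	48068000	48068299	same	8	01	F	FALSE
IGHV8-18	Oncmyk	A	omy13	48072000	48072299	same	8	01	F	FALSE
IGHV8-19	Oncmyk	A	omy13	48076000	48076299	same	8	01	F	FALSE
IGHV8-20	Oncmyk	A	omy13	48080000	48080299	same	8	01	F	FALSE
IGHV8-21	Oncmyk	A	omy13	48084000	48084299	same	8	01	ORF	FALSE
IGHV8-22	Oncmyk	A	omy13	48088000	48088299	same	8	01	P	TRUE
IGHV9-23	Oncmyk	A	omy13	48092000	48092299	same	9	01	F	FALSE
IGHV9-24	Oncmyk	A	omy13	48096000	48096299	same	9	01	F	FALSE
IGHV9-25	Oncmyk	A	omy13	48100000	48100299	same	9	01	F	FALSE
IGHV9-26	Oncmyk	A	omy13	48104000	48104299	same	9	01	P	TRUE
IGHV9D-33	Oncmyk	B	omy12	81668000	81668299	same	9	01	F	FALSE
IGHV10-27	Oncmyk	A	omy13	48108000	48108299	same	10	01	F	FALSE
IGHV10D-34	Oncmyk	B	omy12	81664000	81664299	same	10	01	F	FALSE
IGHV10D-35	Oncmyk	B	omy12	81660000	81660299	same	10	01	F	FALSE
IGHV10D-36	Oncmyk	B	omy12	81656000	81656299	same	10	01	F	FALSE
IGHV11-28	Oncmyk	A	omy13	48112000	48112299	same	11	01	F	FALSE
IGHV12D-37	Oncmyk	B	omy12	81652000	81652299	same	12	01	F	FALSE
IGHV12D-38	Oncmyk	B	omy12	81648000	81648299	same	12	01	F	FALSE
IGHV12D-39	Oncmyk	B	omy12	81644000	81644299	same	12	01	F	FALSE
IGHV12D-40	Oncmyk	B	omy12	81640000	81640299	same	12	01	F	FALSE
IGHV14-29	Oncmyk	A	omy13	48116000	48116299	same	14	01	P	TRUE
IGHV15D-41	Oncmyk	B	omy12	81636000	81636299	same	15	01	F	FALSE
IGHV15D-42	Oncmyk	B	omy12	81632000	81632299	same	15	01	P	TRUE
IGHV15D-43	Oncmyk	B	omy12	81628000	81628299	same	15	01	P	TRUE
IGHV16-30	Oncmyk	A	omy13	48120000	48120299	same	16	01	ORF	FALSE
IGHV16-31	Oncmyk	A	omy13	48124000	48124299	same	16	01	ORF	FALSE
IGHV16-32	Oncmyk	A	omy13	48128000	48128299	same	16	01	P	TRUE
IGHV16-33	Oncmyk	A	omy13	48132000	48132299	same	16	01	P	TRUE
IGHV16D-44	Oncmyk	B	omy12	81624000	81624299	same	16	01	P	TRUE
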