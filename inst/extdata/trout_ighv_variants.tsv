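# Per-gene SNP and indel counts in rainbow trout IGHV genes and pseudogenes
# across 19 isogenic lines, transcribed verbatim from the published summary
# table. One row per gene. `ns` is the non-silent SNP count (reported for
# functional genes only; NA for pseudogenes). Coordinate pairs printed in
# reverse order (start > stop) encode opposite gene polarity and are kept
# verbatim here; loaders normalize them. The row name "IGH IGHV10-47"
# reproduces a printed stray token, normalized on load.
chromosome	start	stop	name	class	snp	ns	indel
Chr12	81322385	81322680	IGHV6D-76	functional	2	1	0
Chr12	81335727	81336024	IGHV1D-73	functional	2	2	0
Chr12	81339680	81339363	IGHV12D-71	functional	1	0	0
Chr12	81365089	81365411	IGHV15D-69	functional	0	0	0
Chr12	81365950	81366255	IGHV2D-68	functional	0	0	0
Chr12	81395848	81396168	IGHV7D-62	functional	0	0	0
Chr12	81397765	81398073	IGHV4D-60	functional	0	0	0
Chr12	81422492	81422803	IGHV15D-54	functional	0	0	0
Chr12	81436861	81437166	IGHV2D-50	functional	0	0	0
Chr12	81438847	81439169	IGHV15D-49	functional	0	0	0
Chr12	81464500	81464820	IGHV7D-45	functional	0	0	0
Chr12	81465762	81466082	IGHV7D-44	functional	0	0	0
Chr12	81466761	81467069	IGHV4D-43	functional	0	0	0
Chr12	81493829	81494124	IGHV6D-40	functional	0	0	0
Chr12	81529173	81529478	IGHV1D-35	functional	0	0	0
Chr12	81561752	81562063	IGHV3D-30	functional	0	0	0
Chr12	81568866	81569171	IGHV2D-28	functional	0	0	0
Chr12	81595836	81596138	IGHV10D-26	functional	2	0	0
Chr12	81605108	81605419	IGHV4D-24	functional	1	0	0
Chr12	81618381	81618689	IGHV4D-23	functional	2	2	0
Chr12	81649810	81650108	IGHV1D-17	functional	5	3	0
Chr12	81653372	81653678	IGHV1D-16	functional	0	0	0
Chr12	81661001	81661301	IGHV1D-15	functional	0	0	0
Chr12	81675466	81675769	IGHV1D-12	functional	2	2	0
Chr12	81696523	81696828	IGHV2D-11	functional	1	0	0
Chr12	81700731	81701033	IGHV10D-9	functional	0	0	0
Chr12	81705764	81706066	IGHV10D-7	functional	2	1	0
Chr12	81717198	81717494	IGHV6D-5	functional	3	2	0
Chr12	81737673	81737973	IGHV1D-4	functional	0	0	0
Chr12	81312817	81313128	IGHV16D-79	pseudogene	3	NA	0
Chr12	81318367	81318661	IGHV15D-78	pseudogene	5	NA	1
Chr12	81320821	81321111	IGHV1D-77	pseudogene	1	NA	0
Chr12	81332711	81333058	IGHV3D-75	pseudogene	2	NA	2
Chr12	81333678	81333986	IGHV1D-74	pseudogene	1	NA	0
Chr12	81336977	81337276	IGHV4D-72	pseudogene	0	NA	0
Chr12	81383887	81384159	IGHV1D-65	pseudogene	0	NA	0
Chr12	81384684	81384968	IGHV6D-64	pseudogene	0	NA	0
Chr12	81388213	81388533	IGHV1D-63	pseudogene	1	NA	1
Chr12	81396766	81397086	IGHV7D-61	pseudogene	0	NA	0
Chr12	81398323	81398601	IGHV1D-59	pseudogene	0	NA	0
Chr12	81399513	81399812	IGHV4D-58	pseudogene	0	NA	0
Chr12	81401688	81402032	IGHV12D-57	pseudogene	0	NA	0
Chr12	81402044	81401727	IGHV12D-56	pseudogene	0	NA	0
Chr12	81421382	81421689	IGHV16D-55	pseudogene	11	NA	0
Chr12	81434530	81434810	IGHV2D-52	pseudogene	0	NA	0
Chr12	81435683	81435988	IGHV2D-51	pseudogene	0	NA	0
Chr12	81447972	81448244	IGHV1D-48	pseudogene	0	NA	0
Chr12	81448773	81449068	IGHV6D-47	pseudogene	0	NA	0
Chr12	81453306	81453632	IGHV1D-46	pseudogene	0	NA	0
Chr12	81467316	81467588	IGHV1D-42	pseudogene	0	NA	0
Chr12	81481949	81482241	IGHV16D-41	pseudogene	0	NA	0
Chr12	81511235	81511555	IGHV1D-39	pseudogene	2	NA	0
Chr12	81514353	81514683	IGHV1D-38	pseudogene	0	NA	0
Chr12	81516973	81517272	IGHV4D-37	pseudogene	0	NA	0
Chr12	81519248	81519565	IGHV12D-36	pseudogene	1	NA	1
Chr12	81548116	81548425	IGHV16D-34	pseudogene	0	NA	0
Chr12	81550863	81551152	IGHV16D-33	pseudogene	0	NA	0
Chr12	81558855	81559137	IGHV15D-32	pseudogene	0	NA	0
Chr12	81560796	81561107	IGHV12D-31	pseudogene	0	NA	0
Chr12	81567432	81567712	IGHV2D-29	pseudogene	0	NA	0
Chr12	81594924	81595202	IGHV6D-27	pseudogene	1	NA	0
Chr12	81598873	81599174	IGHV1D-25	pseudogene	0	NA	0
Chr12	81618939	81619217	IGHV1D-22	pseudogene	11	NA	2
Chr12	81628800	81629081	IGHV1D-21	pseudogene	2	NA	0
Chr12	81629835	81630118	IGHV8D-20	pseudogene	0	NA	0
Chr12	81630920	81631246	IGHV6D-19	pseudogene	0	NA	0
Chr12	81637541	81637838	IGHV6D-18	pseudogene	0	NA	0
Chr12	81674597	81674901	IGHV4D-13	pseudogene	0	NA	0
Chr12	81699366	81699678	IGHV6D-10	pseudogene	0	NA	0
Chr12	81704399	81704711	IGHV6D-8	pseudogene	0	NA	0
Chr12	81713243	81713531	IGHV6D-6	pseudogene	3	NA	1
Chr12	81745526	81745784	IGHV1D-3	pseudogene	2	NA	0
Chr12	81746308	81746602	IGHV9D-2	pseudogene	1	NA	0
Chr12	81750741	81751044	IGHV16D-1	pseudogene	6	NA	2
Chr12	81671030	81671329	IGHV1D-14	pseudogene	0	NA	0
Chr12	81367086	81367437	IGHV1D-67	pseudogene	0	NA	0
Chr12	81367599	81367922	IGHV15D-66	pseudogene	0	NA	0
Chr12	81430263	81430605	IGHV15D-53	pseudogene	0	NA	0
Chr12	81359137	81359442	IGHV1D-70	pseudogene	0	NA	0
Chr12	81676641	81676923	IGHV5D-11	pseudogene	0	NA	0
Chr13	48030797	48031104	IGH IGHV10-47	functional	2	1	0
Chr13	48034515	48034814	IGHV8-46	functional	1	0	0
Chr13	48054181	48054484	IGHV1-42	functional	0	0	0
Chr13	48073234	48073536	IGHV8-40	functional	0	0	0
Chr13	48077115	48077414	IGHV1-39	functional	1	1	0
Chr13	48082080	48082391	IGHV16-37	functional	3	3	0
Chr13	48093298	48093597	IGHV1-36	functional	0	0	0
Chr13	48104897	48105217	IGHV6-35	functional	0	0	0
Chr13	48109683	48109994	IGHV14-33	functional	0	0	0
Chr13	48122499	48122783	IGHV6-32	functional	0	0	0
Chr13	48127168	48127466	IGHV6-31	functional	0	0	0
Chr13	48135329	48135631	IGHV8-30	functional	0	0	0
Chr13	48145742	48146047	IGHV2-28	functional	7	3	0
Chr13	48148981	48149284	IGHV11-25	functional	0	0	0
Chr13	48164983	48165317	IGHV9-23	functional	4	3	0
Chr13	48166898	48167189	IGHV4-22	functional	9	7	0
Chr13	48168162	48168465	IGHV1-21	functional	5	3	0
Chr13	48174816	48175127	IGHV3-20	functional	4	2	0
Chr13	48191970	48192272	IGHV8-19	functional	6	5	0
Chr13	48201668	48201973	IGHV1-18	functional	2	0	0
Chr13	48222441	48222126	IGHV9-16	functional	1	1	1
Chr13	48223844	48223544	IGHV9-15	functional	4	2	0
Chr13	48237588	48237899	IGHV16-14	functional	6	6	0
Chr13	48243688	48243987	IGHV1-13	functional	3	0	0
Chr13	48250487	48250789	IGHV1-10	functional	0	0	0
Chr13	48257525	48257828	IGHV2-8	functional	2	1	0
Chr13	48307972	48307670	IGHV8-5	functional	7	2	0
Chr13	48312160	48311865	IGHV6-4	functional	0	0	0
Chr13	48327417	48327761	IGHV1-2	functional	0	0	0
Chr13	48138071	48138427	IGHV8-29	pseudogene	0	NA	0
Chr13	48027352	48027666	IGHV15-48	pseudogene	7	NA	0
Chr13	48046874	48047207	IGHV9-45	pseudogene	1	NA	0
Chr13	48048080	48048362	IGHV4-44	pseudogene	0	NA	0
Chr13	48051342	48051671	IGHV1-43	pseudogene	2	NA	0
Chr13	48068027	48068332	IGHV1-41	pseudogene	0	NA	0
Chr13	48079966	48080277	IGHV16-38	pseudogene	1	NA	0
Chr13	48108554	48108889	IGHV9-34	pseudogene	0	NA	0
Chr13	48146928	48147231	IGHV2-27	pseudogene	3	NA	0
Chr13	48147810	48148106	IGHV6-26	pseudogene	3	NA	0
Chr13	48157816	48158168	IGHV9-24	pseudogene	5	NA	2
Chr13	48211869	48212178	IGHV7-17	pseudogene	3	NA	0
Chr13	48244719	48245034	IGHV10-12	pseudogene	3	NA	0
Chr13	48245867	48246172	IGHV8-11	pseudogene	2	NA	0
Chr13	48254879	48254570	IGHV16-9	pseudogene	0	NA	0
Chr13	48279548	48279841	IGHV1-7	pseudogene	0	NA	0
Chr13	48280387	48280681	IGHV4-6	pseudogene	4	NA	1
Chr13	48316059	48315761	IGHV6-3	pseudogene	3	NA	0
Chr13	48339577	48339885	IGHV4-1	pseudogene	0	NA	0
Chr13	48076216	48076475	IGHV13-39	pseudogene	4	NA	0
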