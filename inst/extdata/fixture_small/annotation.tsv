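cell_id	sample_id	group	clinical_score	n_genes_detected	mito_fraction	uniquely_mapped_reads	n_splices
CTRL1_c1	CTRL1	control	0	6089	0.050551314673452079	58752	6876
CTRL1_c2	CTRL1	control	0	6265	0.055770544047348054	61586	7555
CTRL1_c3	CTRL1	control	0	2736	0.035932534832559274	51615	7358
CTRL1_c4	CTRL1	control	0	7289	0.05426052889324192	59368	7409
CTRL1_c5	CTRL1	control	0	5299	0.051579466929911152	46593	5419
CTRL1_c6	CTRL1	control	0	7113	0.062966150315547906	46274	4455
CTRL1_c7	CTRL1	control	0	6442	0.03114571746384872	44368	5363
CTRL1_c8	CTRL1	control	0	9904	0.098876009834913944	59918	7174
CTRL1_c9	CTRL1	control	0	7737	0.12276519666269368	50202	6346
CTRL1_c10	CTRL1	control	0	6665	0.043354365967840425	32182	4194
CTRL1_c11	CTRL1	control	0	4948	0.033347584437793926	37518	4582
CTRL1_c12	CTRL1	control	0	6581	0.042352051427491016	56541	6483
CTRL1_c13	CTRL1	control	0	4389	0.034866093986862051	67859	7733
CTRL1_c14	CTRL1	control	0	5099	0.058960692871419057	57660	7111
CTRL1_c15	CTRL1	control	0	5869	0.041061398411776098	41394	4912
CTRL1_c16	CTRL1	control	0	4023	0.024939250543547769	41295	4583
CTRL1_c17	CTRL1	control	0	6050	0.053440840052503283	50775	5672
CTRL1_c18	CTRL1	control	0	5458	0.028354925446101197	76786	10943
CTRL1_c19	CTRL1	control	0	5287	0.073073308270676693	58566	8033
CTRL1_c20	CTRL1	control	0	6161	0.046770085667978696	55980	6561
HSCR1_c1	HSCR1	S	1	5437	0.03521842194378598	41217	5810
HSCR1_c2	HSCR1	S	1	5781	0.05182072829131653	51755	7833
HSCR1_c3	HSCR1	S	1	5231	0.026078376092472513	49736	6788
HSCR1_c4	HSCR1	S	1	5842	0.091504605936540431	35626	4859
HSCR1_c5	HSCR1	S	1	5672	0.020327349524815207	51929	6955
HSCR1_c6	HSCR1	S	1	6583	0.052851711026615969	41559	5512
HSCR1_c7	HSCR1	S	1	6516	0.05178663904712584	42783	6293
HSCR1_c8	HSCR1	S	1	6539	0.081908380831750047	39342	5759
HSCR1_c9	HSCR1	S	1	5934	0.036812787599903127	41890	6300
HSCR1_c10	HSCR1	S	1	6032	0.027559055118110236	45636	6227
HSCR1_c11	HSCR1	S	1	5297	0.045829514207149404	53313	7447
HSCR1_c12	HSCR1	S	1	6357	0.047708138447146865	52189	7269
HSCR1_c13	HSCR1	S	1	6865	0.050621045230841342	62541	9119
HSCR1_c14	HSCR1	S	1	5472	0.023693117713426099	58216	7642
HSCR1_c15	HSCR1	S	1	5929	0.042682926829268296	55677	8487
HSCR1_c16	HSCR1	S	1	5809	0.38223323237616569	42522	6098
HSCR1_c17	HSCR1	S	1	6206	0.029646350639578632	45318	6076
HSCR1_c18	HSCR1	S	1	5769	0.025165562913907286	43287	6168
HSCR1_c19	HSCR1	S	1	6470	0.062160176340925792	60754	7946
HSCR1_c20	HSCR1	S	1	6187	0.038387185860259597	41387	5841
HSCR2_c1	HSCR2	L	5	8290	0.019833948339483393	72338	13823
HSCR2_c2	HSCR2	L	5	5272	0.020873598763045998	56180	9885
HSCR2_c3	HSCR2	L	5	6155	0.018956115294728643	55587	10632
HSCR2_c4	HSCR2	L	5	5654	0.019816844317670019	48155	9565
HSCR2_c5	HSCR2	L	5	5745	0.017145462836297309	58368	12074
HSCR2_c6	HSCR2	L	5	6006	0.014832753140608446	35059	7181
HSCR2_c7	HSCR2	L	5	5072	0.024745853397538792	59929	10832
HSCR2_c8	HSCR2	L	5	5415	0.022585034013605444	64136	13740
HSCR2_c9	HSCR2	L	5	5909	0.014632268001540239	50400	10353
HSCR2_c10	HSCR2	L	5	5950	0.0159870250231696	80802	15464
HSCR2_c11	HSCR2	L	5	6639	0.048915355168013611	57675	11824
HSCR2_c12	HSCR2	L	5	6399	0.026384207992296582	51049	10483
HSCR2_c13	HSCR2	L	5	7445	0.017969195664575013	32019	6246
HSCR2_c14	HSCR2	L	5	6115	0.0060342193706080047	61115	11949
HSCR2_c15	HSCR2	L	5	6681	0.019499588864090214	45163	9337
HSCR2_c16	HSCR2	L	5	7679	0.0060478569550354985	30819	6812
HSCR2_c17	HSCR2	L	5	550	0.01913265306122449	53448	10085
HSCR2_c18	HSCR2	L	5	11178	0.039627039627039624	50651	10607
HSCR2_c19	HSCR2	L	5	4827	0.013790386130811664	41249	8122
HSCR2_c20	HSCR2	L	5	5898	0.017100977198697069	41565	8126
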