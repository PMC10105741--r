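section	key	value
sample_severity	CTRL1	0
sample_severity	HSCR1	0.20000000000000001
sample_severity	HSCR2	1
cell_severity	CTRL1_c1	0
cell_severity	CTRL1_c2	0.013664807985229078
cell_severity	CTRL1_c3	0.037215131350389757
cell_severity	CTRL1_c4	0
cell_severity	CTRL1_c5	0.0076940352699881248
cell_severity	CTRL1_c6	0.014928329700159289
cell_severity	CTRL1_c7	0
cell_severity	CTRL1_c8	0.03098785312868654
cell_severity	CTRL1_c9	0.025653463803485339
cell_severity	CTRL1_c10	0
cell_severity	CTRL1_c11	0.02115419181272216
cell_severity	CTRL1_c12	0.00012020049057137353
cell_severity	CTRL1_c13	0
cell_severity	CTRL1_c14	0
cell_severity	CTRL1_c15	0.021714151643810065
cell_severity	CTRL1_c16	0.0024226806876429361
cell_severity	CTRL1_c17	0
cell_severity	CTRL1_c18	0.034890166499882115
cell_severity	CTRL1_c19	0
cell_severity	CTRL1_c20	0.0041263758989069652
cell_severity	HSCR1_c1	0.19734364364129361
cell_severity	HSCR1_c2	0.17837192561920429
cell_severity	HSCR1_c3	0.20812683809526344
cell_severity	HSCR1_c4	0.1388500680595538
cell_severity	HSCR1_c5	0.18808519986933803
cell_severity	HSCR1_c6	0.17047376205533471
cell_severity	HSCR1_c7	0.18870068389326483
cell_severity	HSCR1_c8	0.19967154633178275
cell_severity	HSCR1_c9	0.14691298286460611
cell_severity	HSCR1_c10	0.21024962444011702
cell_severity	HSCR1_c11	0.14819268421669218
cell_severity	HSCR1_c12	0.15341132010261188
cell_severity	HSCR1_c13	0.1537928610435782
cell_severity	HSCR1_c14	0.20039603126771999
cell_severity	HSCR1_c15	0.17542872874741045
cell_severity	HSCR1_c16	0.23493911506711487
cell_severity	HSCR1_c17	0.23880357513970576
cell_severity	HSCR1_c18	0.19228448275121079
cell_severity	HSCR1_c19	0.18077211992984377
cell_severity	HSCR1_c20	0.1866264276012248
cell_severity	HSCR2_c1	0.98133644676274523
cell_severity	HSCR2_c2	0.98171080221450513
cell_severity	HSCR2_c3	0.99464488993321121
cell_severity	HSCR2_c4	0.97566043424990423
cell_severity	HSCR2_c5	1
cell_severity	HSCR2_c6	1
cell_severity	HSCR2_c7	1
cell_severity	HSCR2_c8	0.99711976390877355
cell_severity	HSCR2_c9	1
cell_severity	HSCR2_c10	0.94037005694170561
cell_severity	HSCR2_c11	1
cell_severity	HSCR2_c12	1
cell_severity	HSCR2_c13	1
cell_severity	HSCR2_c14	1
cell_severity	HSCR2_c15	1
cell_severity	HSCR2_c16	1
cell_severity	HSCR2_c17	1
cell_severity	HSCR2_c18	1
cell_severity	HSCR2_c19	1
cell_severity	HSCR2_c20	1
module_label	G0001	1
module_label	G0002	1
module_label	G0003	2
module_label	G0004	2
module_label	G0005	3
module_label	G0006	3
module_label	G0007	4
module_label	G0008	4
module_label	G0009	none
module_label	G0010	none
module_label	G0011	none
module_label	G0012	none
module_label	G0013	none
module_label	G0014	none
module_label	G0015	none
module_label	G0016	none
module_label	G0017	none
module_label	MT-G0018	none
module_label	G0019	none
module_label	G0020	none
switch_center	G0009	0.21659607899375261
switch_center	G0010	0.19287819355726243
switch_direction	G0009	up
switch_direction	G0010	down
hub_gene	hub	G0011
hub_target_class	G0001	none
hub_target_class	G0002	none
hub_target_class	G0003	none
hub_target_class	G0004	none
hub_target_class	G0005	none
hub_target_class	G0006	none
hub_target_class	G0007	none
hub_target_class	G0008	none
hub_target_class	G0009	none
hub_target_class	G0010	none
hub_target_class	G0011	none
hub_target_class	G0012	activated
hub_target_class	G0013	activated
hub_target_class	G0014	repressed
hub_target_class	G0015	repressed
hub_target_class	G0016	none
hub_target_class	G0017	none
hub_target_class	MT-G0018	none
hub_target_class	G0019	none
hub_target_class	G0020	none
driver_event	driver	E001
driver_target_class	E001	none
driver_target_class	E002	enhanced
driver_target_class	E003	repressed
driver_target_class	E004	enhanced
driver_target_class	E005	repressed
driver_target_class	E006	none
mxe_pair	first	E004
mxe_pair	second	E005
binding_genes	G0012	G0012
binding_genes	G0013	G0013
binding_genes	G0014	G0014
binding_genes	G0015	G0015
binding_genes	G0019	G0019
binding_genes	G0020	G0020
motif_gene_hits	G0001	0
motif_gene_hits	G0002	0
motif_gene_hits	G0003	0
motif_gene_hits	G0004	0
motif_gene_hits	G0005	0
motif_gene_hits	G0006	2
motif_gene_hits	G0007	0
motif_gene_hits	G0008	0
motif_gene_hits	G0009	0
motif_gene_hits	G0010	0
motif_gene_hits	G0011	0
motif_gene_hits	G0012	3
motif_gene_hits	G0013	4
motif_gene_hits	G0014	3
motif_gene_hits	G0015	2
motif_gene_hits	G0016	0
motif_gene_hits	G0017	0
motif_gene_hits	MT-G0018	0
motif_gene_hits	G0019	0
motif_gene_hits	G0020	0
motif_target_events	E002	E002
motif_target_events	E003	E003
motif_target_events	E004	E004
motif_target_events	E005	E005
motif_target_events	E006	E006
gene_role	G0001	module1
gene_role	G0002	module1
gene_role	G0003	module2
gene_role	G0004	module2
gene_role	G0005	module3
gene_role	G0006	module3
gene_role	G0007	module4
gene_role	G0008	module4
gene_role	G0009	switch
gene_role	G0010	switch
gene_role	G0011	hub
gene_role	G0012	hub_activated
gene_role	G0013	hub_activated
gene_role	G0014	hub_repressed
gene_role	G0015	hub_repressed
gene_role	G0016	nuisance
gene_role	G0017	nuisance
gene_role	MT-G0018	mito
gene_role	G0019	none
gene_role	G0020	none
qc_fail	CTRL1_c3	low_genes
qc_fail	CTRL1_c8	high_genes
qc_fail	HSCR1_c16	high_mito
qc_fail	HSCR2_c17	low_genes
qc_fail	HSCR2_c18	high_genes
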