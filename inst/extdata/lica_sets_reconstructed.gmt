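aDC	cell: activated dendritic cells (reconstructed markers)	CCL1	EBI3	IDO1	LAMP3	OAS3	CD83	CCR7	INDO
B_cells	cell: B cells (reconstructed markers)	CD19	MS4A1	CD79A	CD79B	BLK	CR2	FCRL2	IGHM	TCL1A	SPIB	BLNK
CD8_T_cells	cell: CD8 T cells (reconstructed markers)	CD8A	CD8B	GZMM	FLT3LG	PRF1	DNAJB1	CD3D	CD3E	THUMPD1	TRA
DC	cell: dendritic cells (reconstructed markers)	CCL13	CD209	HSD11B1	CLEC4C	NPR1	ITGAX	CD1C	CLEC10A
iDC	cell: immature dendritic cells (reconstructed markers)	CD1A	CD1B	CD1E	F13A1	SYT17	CTNS	MMP12	FABP4	VASH1
Macrophages	cell: macrophages (reconstructed markers)	CD68	CD163	MSR1	MRC1	CSF1R	FCGR1A	MARCO	CTSK	ACP5	LGMN
Mast_cells	cell: mast cells (reconstructed markers)	TPSAB1	TPSB2	CPA3	MS4A2	CMA1	KIT	HDC	SLC18A2
Neutrophils	cell: neutrophils (reconstructed markers)	FCGR3B	CSF3R	CEACAM3	S100A12	FPR1	SIGLEC5	CXCR2	CXCR1	MME
NK_cells	cell: natural killer cells (reconstructed markers)	KLRD1	KLRC1	KLRF1	NCR1	NCR3	KIR2DL1	KIR2DL3	KIR3DL1	XCL1	XCL2	NKG7
pDC	cell: plasmacytoid dendritic cells (reconstructed markers)	IL3RA	LILRA4	CLEC4C	GZMB	IRF7	TCF4	PTCRA	SERPINF1
T_helper_cells	cell: T helper cells (reconstructed markers)	CD4	CD28	ICOS	CD40LG	IL7R	ANP32B	ASF1A	BATF
Tfh	cell: follicular helper T cells (reconstructed markers)	CXCR5	BCL6	PDCD1	ICOS	IL21	CXCL13	SH2D1A	MAF	TOX2
Th1_cells	cell: type-1 helper T cells (reconstructed markers)	TBX21	IFNG	IL12RB2	STAT4	CXCR3	CCR5	IL2	LTA	HAVCR2
Th2_cells	cell: type-2 helper T cells (reconstructed markers)	GATA3	IL4	IL5	IL13	CCR4	PTGDR2	STAT6	IL4R	CXCR6
Treg	cell: regulatory T cells (reconstructed markers)	FOXP3	IL2RA	CTLA4	IKZF2	TNFRSF18	CCR8	TNFRSF4	ENTPD1	LRRC32
APC_co_inhibition	function: antigen-presenting-cell co-inhibition (reconstructed)	CD274	PDCD1LG2	VTCN1	LGALS9	BTN3A1	BTN3A2	SLAMF7
APC_co_stimulation	function: antigen-presenting-cell co-stimulation (reconstructed)	CD40	CD80	CD86	ICOSLG	TNFSF4	TNFSF9	CD70	TNFSF15
CCR	function: chemokine and chemokine receptor activity (reconstructed)	CCL2	CCL3	CCL4	CCL5	CXCL9	CXCL10	CXCL11	CCR1	CCR2	CCR5	CXCR3	CXCR4
Check_point	function: immune checkpoint expression (reconstructed)	PDCD1	CTLA4	LAG3	HAVCR2	TIGIT	BTLA	CD274	IDO1	VSIR
Cytolytic_activity	function: cytolytic effector activity (reconstructed)	GZMA	PRF1	GZMB	GZMH	GZMK	GNLY	KLRK1	FASLG
HLA	function: HLA expression (reconstructed)	HLA-A	HLA-B	HLA-C	HLA-DPA1	HLA-DPB1	HLA-DQA1	HLA-DQB1	HLA-DRA	HLA-DRB1	HLA-E	HLA-F
Inflammation_promoting	function: inflammation-promoting signals (reconstructed)	IL1A	IL1B	IL6	TNF	IL18	IL12A	IL12B	IFNG	PTGS2	NOS2
MHC_class_I	function: MHC class I antigen presentation (reconstructed)	HLA-A	HLA-B	HLA-C	B2M	TAP1	TAP2	TAPBP	PSMB8	PSMB9
Parainflammation	function: parainflammation (reconstructed)	PLAT	SERPINA3	SAA1	SAA2	CFB	C1QA	C1QB	PTGS2	MX1	OAS1	ISG15
T_cell_co_inhibition	function: T-cell co-inhibition (reconstructed)	PDCD1	CTLA4	LAG3	BTLA	TIGIT	CD160	CD244	LAIR1
T_cell_co_stimulation	function: T-cell co-stimulation (reconstructed)	CD28	ICOS	CD27	TNFRSF9	TNFRSF4	TNFRSF18	CD226	SLAMF1
TIL	function: tumor-infiltrating lymphocyte abundance (reconstructed)	CD3D	CD3E	CD3G	CD2	CD5	CD6	TRAC	TRBC1	LCK	ZAP70
Type_I_IFN_response	function: type I interferon response (reconstructed)	IFIT1	IFIT2	IFIT3	ISG15	MX1	MX2	OAS1	OAS2	OAS3	IRF7	STAT1
Type_II_IFN_response	function: type II interferon response (reconstructed)	IFNG	STAT1	IRF1	GBP1	GBP2	CXCL9	CXCL10	CIITA	SOCS1
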