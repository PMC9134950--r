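Amino_acid_metabolism	TME metabolic category: amino acid metabolism (reconstructed)	SLC1A5	SLC7A5	GLS	GLS2	GLUD1	GOT1	GOT2	ASNS	PSAT1	PHGDH	SHMT1	SHMT2	BCAT1	BCAT2	ASS1
TCA_cycle	TME metabolic category: tricarboxylic acid cycle (reconstructed)	CS	ACO2	IDH1	IDH2	IDH3A	OGDH	SUCLA2	SUCLG1	SDHA	SDHB	FH	MDH1	MDH2
Nucleotide_metabolism	TME metabolic category: nucleotide metabolism (reconstructed)	RRM1	RRM2	TYMS	DHFR	GART	PAICS	ATIC	IMPDH1	IMPDH2	CAD	UMPS	NME1	DCK
Energy_metabolism	TME metabolic category: oxidative phosphorylation and energy (reconstructed)	ATP5F1A	ATP5F1B	ATP5MC1	NDUFA1	NDUFB1	NDUFS1	COX4I1	COX5A	COX6B1	UQCRC1	UQCRC2	CYCS	PPA1
Carbohydrate_metabolism	TME metabolic category: glycolysis and carbohydrate metabolism (reconstructed)	HK1	HK2	GPI	PFKL	PFKM	ALDOA	GAPDH	PGK1	PGAM1	ENO1	PKM	LDHA	SLC2A1	PDK1
Lipid_metabolism	TME metabolic category: fatty acid and lipid metabolism (reconstructed)	FASN	ACACA	SCD	ACLY	CPT1A	CPT2	ACOX1	ACSL1	ACSL4	ACSF2	HMGCR	SREBF1	FABP5	PLIN2
Vitamin_cofactor_metabolism	TME metabolic category: vitamin and cofactor metabolism (reconstructed)	FOLR1	SLC19A1	MTHFR	MTR	BCO1	RDH10	ALDH1A1	ALDH1A2	PNPO	FLAD1	COQ2	COQ7	PANK1
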