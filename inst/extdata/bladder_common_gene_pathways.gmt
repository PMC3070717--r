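KEGG_cardiac_muscle_contraction	Cardiac muscle contraction (KEGG)	70	7169
KEGG_dilated_cardiomyopathy	Dilated cardiomyopathy (KEGG)	70	7169
KEGG_hypertrophic_cardiomyopathy	Hypertrophic cardiomyopathy HCM (KEGG)	70	7169
KEGG_calcium_signaling	Calcium signaling pathway (KEGG)	3973	6870
KEGG_neuroactive_ligand_receptor	Neuroactive ligand-receptor interaction (KEGG)	3973	6870
PC_signaling_by_gpcr	Signaling by GPCR (Pathway Commons)	3973	6870
PC_class_a_rhodopsin_like	Class A/1 rhodopsin-like receptors (Pathway Commons)	3973	6870
WP_striated_muscle_contraction	Striated muscle contraction (WikiPathways)	70	7169
WP_peptide_gpcrs	Peptide GPCRs (WikiPathways)	3973	6870
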