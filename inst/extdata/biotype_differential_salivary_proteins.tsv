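protein_group_id	gene_id	description	direction	fold_change	has_signal_peptide
XP_027839590.1	LOC114121443	actin	down_in_A	0.43	FALSE
XP_027854514.1	LOC114133090	heat shock protein	down_in_A	0.38	FALSE
XP_027853233.1	LOC114132056	heat shock protein	down_in_A	0.46	FALSE
XP_027840464.1	LOC114122099	heat shock protein	down_in_A	0.49	FALSE
XP_027849246.1	LOC114128852	histone H3.3	up_in_A	1.31	FALSE
XP_027845398.1	LOC114125817	apoptosis-stimulating protein	up_in_A	1.24	FALSE
XP_027850174.1	LOC114129582	uncharacterized	down_in_A	0.67	TRUE
XP_027851813.1	LOC114130922	E3 ubiquitin-protein ligase	up_in_A	1.27	FALSE
XP_027837426.1	LOC114119891	uncharacterized	up_in_A	2.42	TRUE
XP_027836138.1	LOC114118907	uncharacterized	down_in_A	3.43	TRUE
XP_027852041.1	LOC114131096	uncharacterized	down_in_A	0.12	TRUE
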