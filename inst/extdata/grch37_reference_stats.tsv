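quantity	value	description
n_junctions	142014	canonical filtered exon-intron junctions (GRCh37, Ensembl 75)
top4_sensitivity_pct	87	AM cryptic donors among the top-4 ranked events
top4_specificity_pct	95	decoy donors outside the top-4 ranked events
delta0.1_sensitivity_pct	75	cryptic donors with donor-gain delta score >= 0.1
delta0.1_specificity_pct	99	decoy donors with delta score < 0.1
pct_decoys_in_db	7	decoy donors present as rare mis-splicing events
pct_am_cryptics_in_db	90	AM cryptic donors present in the database at any rank
pct_decoys_absent_db	91	decoy donors absent from the database
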