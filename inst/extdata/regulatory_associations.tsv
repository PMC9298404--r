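hgvs_c	phenotype	novel_in_study	note
c.28+5872C>T	B3/AB3	FALSE	RUNX1 site; previously described as +5904C>T
c.28+5882C>T	Bweak/ABweak	FALSE	near the RUNX1 motif
c.28+5956T>A	A3	TRUE	first identified in an A3 specimen
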