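# Partial list of suppressor substitutions in the Rad21 N-terminal domain
# (residues 18-87): only the alleles named in running text are included
# (the complete 188-substitution list exists only as a figure matrix).
# Hit counts are unknown and therefore omitted.
# Positions/wild-type residues match the packaged synthetic Rad21-NTD region.
position	wt_aa	mut_aa
42	H	P
53	A	V
59	Q	R
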