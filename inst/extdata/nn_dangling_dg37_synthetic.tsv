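# SYNTHETIC stand-in table of DNA dangling-end free energies.
# dG37 in kcal/mol for a single unpaired base X stacking on a terminal
# Watson-Crick pair whose base on the same strand as X is `pair_base`.
# side = 5p (X dangles from the 5' end of its strand) or 3p (3' end).
# These values are NOT a verified transcription of the published
# dangling-end set (Bommarito et al. 2000) cited by the unified NN
# literature; they reproduce its qualitative structure (3' dangling ends
# mostly stabilizing, 5' ends weaker and occasionally destabilizing,
# purines stacking better than pyrimidines) with magnitudes in the
# published -0.96..+0.48 kcal/mol range. Treated as temperature
# independent. Replace with the published table for quantitative work.
# version: synthetic-dangling-v1
side	dangle_base	pair_base	dG37
5p	A	A	-0.51
5p	A	C	-0.96
5p	A	G	-0.58
5p	A	T	-0.50
5p	C	A	-0.42
5p	C	C	-0.52
5p	C	G	-0.34
5p	C	T	-0.02
5p	G	A	-0.62
5p	G	C	-0.72
5p	G	G	-0.56
5p	G	T	0.48
5p	T	A	-0.71
5p	T	C	-0.58
5p	T	G	-0.61
5p	T	T	-0.10
3p	A	A	-0.12
3p	A	C	-0.38
3p	A	G	-0.14
3p	A	T	-0.29
3p	C	A	0.28
3p	C	C	-0.20
3p	C	G	-0.31
3p	C	T	-0.01
3p	G	A	-0.01
3p	G	C	-0.44
3p	G	G	-0.26
3p	G	T	-0.07
3p	T	A	0.13
3p	T	C	-0.34
3p	T	G	-0.60
3p	T	T	0.10
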