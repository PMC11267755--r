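id	name	role	class	formula	mono_mass	nominal_mass
Gly	glycine	residue	proteinogenic	C2H3NO	57.02146	57
Ala	alanine	residue	proteinogenic	C3H5NO	71.03711	71
Ser	serine	residue	proteinogenic	C3H5NO2	87.03203	87
Pro	proline	residue	proteinogenic	C5H7NO	97.05276	97
Val	valine	residue	proteinogenic	C5H9NO	99.06841	99
Thr	threonine	residue	proteinogenic	C4H7NO2	101.04768	101
Cys	cysteine	residue	proteinogenic	C3H5NOS	103.00918	103
Leu/Ile	leucine or isoleucine (isobaric)	residue	proteinogenic	C6H11NO	113.08406	113
Asn	asparagine	residue	proteinogenic	C4H6N2O2	114.04293	114
Asp	aspartate	residue	proteinogenic	C4H5NO3	115.02694	115
Gln	glutamine	residue	proteinogenic	C5H8N2O2	128.05858	128
Lys	lysine	residue	proteinogenic	C6H12N2O	128.09496	128
Glu	glutamate	residue	proteinogenic	C5H7NO3	129.04259	129
Met	methionine	residue	proteinogenic	C5H9NOS	131.04048	131
His	histidine	residue	proteinogenic	C6H7N3O	137.05891	137
Phe	phenylalanine	residue	proteinogenic	C9H9NO	147.06841	147
Arg	arginine	residue	proteinogenic	C6H12N4O	156.10111	156
Tyr	tyrosine	residue	proteinogenic	C9H9NO2	163.06333	163
Trp	tryptophan	residue	proteinogenic	C11H10N2O	186.07931	186
Orn	ornithine	residue	nonproteinogenic	C5H10N2O	114.07931	114
Dab	L-2,4-diaminobutyrate	residue	nonproteinogenic	C4H8N2O	100.06366	100
fOHOrn	L-N5-formyl-N5-hydroxy-ornithine	residue	nonproteinogenic	C6H10N2O3	158.06914	158
azHA	4-azido-L-homoalanine	residue	nonproteinogenic	C4H6N4O	126.05416	126
ChrSuc	PVD chromophore-acyl (succinate)	chromophore_acyl	chromophore	C17H15N3O6	357.09609	357
ChrSucA	PVD chromophore-acyl (succinamide)	chromophore_acyl	chromophore	C17H16N4O5	356.11207	356
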