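id	class	name	formula	mass
ala	amino_acid	L-alanine residue	C3H5NO	71.079
arg	amino_acid	L-arginine residue	C6H12N4O	156.189
asn	amino_acid	L-asparagine residue	C4H6N2O2	114.104
asp	amino_acid	L-aspartate residue	C4H5NO3	115.088
cys	amino_acid	L-cysteine residue	C3H5NOS	103.139
gln	amino_acid	L-glutamine residue	C5H8N2O2	128.131
glu	amino_acid	L-glutamate residue	C5H7NO3	129.115
gly	amino_acid	glycine residue	C2H3NO	57.052
his	amino_acid	L-histidine residue	C6H7N3O	137.142
ile	amino_acid	L-isoleucine residue	C6H11NO	113.16
leu	amino_acid	L-leucine residue	C6H11NO	113.16
lys	amino_acid	L-lysine residue	C6H12N2O	128.175
met	amino_acid	L-methionine residue	C5H9NOS	131.193
phe	amino_acid	L-phenylalanine residue	C9H9NO	147.177
pro	amino_acid	L-proline residue	C5H7NO	97.117
ser	amino_acid	L-serine residue	C3H5NO2	87.078
thr	amino_acid	L-threonine residue	C4H7NO2	101.105
trp	amino_acid	L-tryptophan residue	C11H10N2O	186.214
tyr	amino_acid	L-tyrosine residue	C9H9NO2	163.176
val	amino_acid	L-valine residue	C5H9NO	99.133
amp	rna	AMP residue	C10H12N5O6P	329.209
gmp	rna	GMP residue	C10H12N5O7P	345.208
cmp	rna	CMP residue	C9H12N3O7P	305.183
ump	rna	UMP residue	C9H11N2O8P	306.167
damp	dna	dAMP residue	C10H12N5O5P	313.21
dgmp	dna	dGMP residue	C10H12N5O6P	329.209
dcmp	dna	dCMP residue	C9H12N3O6P	289.184
dtmp	dna	dTMP residue	C10H13N2O7P	304.195
pe_bb	lipid_backbone	phosphatidylethanolamine backbone (glycerophosphoethanolamine)	C5H14NO6P	215.142
pg_bb	lipid_backbone	phosphatidylglycerol backbone (glycerophosphoglycerol)	C6H15O8P	246.152
clpn_bb	lipid_backbone	cardiolipin backbone (bis(glycerophospho)glycerol)	C9H22O13P2	400.21
acyl_160	acyl	palmitoyl residue (C16:0 acid minus H2O)	C16H30O	238.415
acyl_161	acyl	palmitoleoyl residue (C16:1)	C16H28O	236.399
acyl_181	acyl	cis-vaccenoyl residue (C18:1)	C18H32O	264.453
lps	lps	LPS aggregate, synthetic approximation of lipid A + core oligosaccharide without CDP-ethanolamine	C100H180N2O60P3	2463.416
glycogen	carbohydrate	glycogen glucosyl residue	C6H10O5	162.141
murein	peptidoglycan	peptidoglycan repeat unit (GlcNAc-MurNAc-tetrapeptide), approximate	C40H62N8O21	990.971
nad	cofactor	NAD	C21H26N7O14P2	662.422
nadp	cofactor	NADP	C21H25N7O17P3	740.385
fad	cofactor	FAD	C27H31N9O15P2	783.541
coa	cofactor	coenzyme A	C21H34N7O16P3S	765.518
ribflv	cofactor	riboflavin	C17H20N4O6	376.369
thf	cofactor	tetrahydrofolate	C19H21N7O6	443.42
atp	energy	ATP	C10H16N5O13P3	507.182
adp	energy	ADP	C10H15N5O10P2	427.203
pi	energy	orthophosphate	H3PO4	97.994
h2o	energy	water	H2O	18.015
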