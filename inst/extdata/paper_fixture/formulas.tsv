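species	formula	charge
cytosine	C4H5N3O	0
prpp	C5H13O14P3	0
cmp	C9H14N3O8P	0
diphosphate	H4O7P2	0
2-oxoglutarate	C5H6O5	0
2-hydroxyglutarate	C5H8O5	0
nadph	C21H30N7O17P3	0
nadp+	C21H28N7O17P3	1
h+	H	1
bicarbonate	CHO3	-1
orthophosphate	H3O4P	0
carboxyphosphate	CH3O6P	0
h2o	H2O	0
acetoacetyl-coa	C25H40N7O18P3S	0
citrate	C6H8O7	0
acetoacetate	C4H6O3	0
citryl-coa	C27H42N7O22P3S	0
l-glutamate	C5H9NO4	0
3-cyano-l-alanine	C4H6N2O2	0
gamma-glutamyl-beta-cyanoalanine	C9H13N3O5	0
thf	C19H23N7O6	0
thf-l-glutamate	C24H30N8O9	0
atp	C10H16N5O13P3	0
adp	C10H15N5O10P2	0
propanoyl-coa	C24H40N7O17P3S	0
acetyl-coa	C23H38N7O17P3S	0
2-methylacetoacetyl-coa	C26H42N7O18P3S	0
coa	C21H36N7O16P3S	0
d-ribulose-5-phosphate	C5H11O8P	0
d-ribulose-1,5-bisphosphate	C5H12O11P2	0
d-gluconate	C6H12O7	0
2-keto-d-gluconate	C6H10O7	0
nad+	C21H27N7O14P2	1
nadh	C21H29N7O14P2	0
5-amino-4-imidazolecarboxamide	C4H6N4O	0
phosphoribosyl-aica	C9H15N4O8P	0
pyruvate	C3H4O3	0
glyoxylate	C2H2O3	0
4-hydroxy-2-oxoglutarate	C5H6O6	0
guanine	C5H5N5O	0
gmp	C10H14N5O8P	0
glycerate	C3H6O4	0
co2	CO2	0
tartrate	C4H6O6	0
oxaloacetate	C4H4O5	0
4-carboxy-4-hydroxy-2-oxoadipate	C7H8O8	0
l-histidine	C6H9N3O2	0
imidazol-5-yl-pyruvate	C6H6N2O3	0
ammonia	H3N	0
geranyl-diphosphate	C10H20O7P2	0
4-hydroxybenzoate	C7H6O3	0
geranyl-hydroxybenzoate	C17H22O3	0
d-alanine	C3H7NO2	0
2-aminoacrylate	C3H5NO2	0
phenylpyruvate	C9H8O3	0
phenyllactate	C9H10O3	0
l-serine	C3H7NO3	0
aminomalonate	C3H5NO4	0
n-acetylornithine	C7H14N2O3	0
n-acetylputrescine	C6H14N2O	0
n-carbamoyl-l-aspartate	C5H8N2O5	0
3-ureidopropionate	C4H8N2O3	0
d-galactarate	C6H10O8	0
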