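candidate_id	side	species	coeff
c01	S	cytosine	1
c01	S	prpp	1
c01	P	cmp	1
c01	P	diphosphate	1
c02	S	2-oxoglutarate	1
c02	S	nadph	1
c02	S	h+	1
c02	P	2-hydroxyglutarate	1
c02	P	nadp+	1
c03	S	bicarbonate	1
c03	S	orthophosphate	1
c03	P	carboxyphosphate	1
c03	P	h2o	1
c04	S	acetoacetyl-coa	1
c04	S	citrate	1
c04	P	acetoacetate	1
c04	P	citryl-coa	1
c05	S	l-glutamate	1
c05	S	3-cyano-l-alanine	1
c05	P	gamma-glutamyl-beta-cyanoalanine	1
c05	P	h2o	1
c06	S	l-glutamate	1
c06	S	thf	1
c06	S	atp	1
c06	P	thf-l-glutamate	1
c06	P	adp	1
c06	P	orthophosphate	1
c07	S	propanoyl-coa	1
c07	S	acetyl-coa	1
c07	P	2-methylacetoacetyl-coa	1
c07	P	coa	1
c08	S	d-ribulose-5-phosphate	1
c08	S	atp	1
c08	P	d-ribulose-1,5-bisphosphate	1
c08	P	adp	1
c09	S	d-gluconate	1
c09	S	nadp+	1
c09	P	2-keto-d-gluconate	1
c09	P	nadph	1
c09	P	h+	1
c10	S	5-amino-4-imidazolecarboxamide	1
c10	S	prpp	1
c10	P	phosphoribosyl-aica	1
c10	P	diphosphate	1
c11	S	pyruvate	1
c11	S	glyoxylate	1
c11	P	4-hydroxy-2-oxoglutarate	1
c12	S	guanine	1
c12	S	prpp	1
c12	P	gmp	1
c12	P	diphosphate	1
c13	S	glycerate	1
c13	S	co2	1
c13	P	tartrate	1
c14	S	bicarbonate	1
c14	S	atp	1
c14	P	carboxyphosphate	1
c14	P	adp	1
c15	S	pyruvate	1
c15	S	oxaloacetate	1
c15	P	4-carboxy-4-hydroxy-2-oxoadipate	1
c16	S	l-histidine	1
c16	S	h2o	1
c16	S	nadp+	1
c16	P	imidazol-5-yl-pyruvate	1
c16	P	ammonia	1
c16	P	nadph	1
c16	P	h+	1
c17	S	geranyl-diphosphate	1
c17	S	4-hydroxybenzoate	1
c17	P	geranyl-hydroxybenzoate	1
c17	P	diphosphate	1
c18	S	d-alanine	1
c18	S	nadp+	1
c18	P	2-aminoacrylate	1
c18	P	nadph	1
c18	P	h+	1
c19	S	phenylpyruvate	1
c19	S	nadph	1
c19	S	h+	1
c19	P	phenyllactate	1
c19	P	nadp+	1
c20	S	l-serine	1
c20	S	nad+	2
c20	S	h2o	1
c20	P	aminomalonate	1
c20	P	nadh	2
c20	P	h+	2
c21	S	n-acetylornithine	1
c21	P	n-acetylputrescine	1
c21	P	co2	1
c22	S	n-carbamoyl-l-aspartate	1
c22	P	3-ureidopropionate	1
c22	P	co2	1
c23	S	d-gluconate	1
c23	S	nad+	2
c23	S	h2o	1
c23	P	d-galactarate	1
c23	P	nadh	2
c23	P	h+	2
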