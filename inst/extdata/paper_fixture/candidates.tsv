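candidate_id	group	substrate	product	ec	genes	enzyme_name
c01	c1-a	cytosine	cmp	2.4.2.10	b3642	orotate phosphoribosyltransferase
c02	c1-b	2-oxoglutarate	2-hydroxyglutarate	1.1.1.79	b1033	glyoxylate reductase
c03	c1-c	bicarbonate	carboxyphosphate	3.6.1.7	b0968	acylphosphatase
c04	c1-d	acetoacetyl-coa	acetoacetate	2.8.3.10	b0615	citrate CoA-transferase
c05	c2-a	l-glutamate	gamma-glutamyl-beta-cyanoalanine	2.3.2.2		gamma-glutamyltransferase
c06	c2-b	l-glutamate	thf-l-glutamate	6.3.2.17		tetrahydrofolate synthase
c07	c2-c	propanoyl-coa	2-methylacetoacetyl-coa	2.3.1.9		acetoacetyl-CoA thiolase
c08	c2-d	d-ribulose-5-phosphate	d-ribulose-1,5-bisphosphate	2.7.1.19		phosphoribulokinase
c09	c2-e	d-gluconate	2-keto-d-gluconate	1.1.1.215		gluconate 2-dehydrogenase
c10	c2-f	5-amino-4-imidazolecarboxamide	phosphoribosyl-aica	2.4.2.7		AMP pyrophosphorylase
c11	c2-g	pyruvate	4-hydroxy-2-oxoglutarate	4.1.3.24		malyl-CoA lyase
c12	c2-h	guanine	gmp	2.4.2.10	b3642	orotate phosphoribosyltransferase
c13	c2-i	glycerate	tartrate	4.1.1.73		tartrate decarboxylase
c14	c2-j	bicarbonate	carboxyphosphate	3.6.1.7	b0968	acylphosphatase
c15	c3-a	pyruvate	4-carboxy-4-hydroxy-2-oxoadipate	4.1.3.34		citryl-CoA lyase
c16	c3-b	l-histidine	imidazol-5-yl-pyruvate	1.4.1.4		glutamate dehydrogenase
c17	c3-c	geranyl-diphosphate	geranyl-hydroxybenzoate	2.5.1.39		4-hydroxybenzoate transferase
c18	c3-d	d-alanine	2-aminoacrylate	1.3.1.98		UDP-N-acetylmuramate dehydrogenase
c19	c3-e	phenylpyruvate	phenyllactate	1.1.1.100		3-oxoacyl-ACP reductase
c20	c4-a	l-serine	aminomalonate	1.1.1.23		histidinol dehydrogenase
c21	c4-b	n-acetylornithine	n-acetylputrescine	4.1.1.36		PPC decarboxylase
c22	c4-c	n-carbamoyl-l-aspartate	3-ureidopropionate	4.1.1.36		PPC decarboxylase
c23	c4-d	d-gluconate	d-galactarate	1.1.1.23		histidinol dehydrogenase
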