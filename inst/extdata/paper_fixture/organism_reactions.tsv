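substrate	product	ec	genes	equation_of
l-glutamate	gamma-glutamyl-beta-cyanoalanine	2.3.2.2		c05
l-glutamate	thf-l-glutamate	6.3.2.17		c06
propanoyl-coa	2-methylacetoacetyl-coa	2.3.1.9		c07
d-ribulose-5-phosphate	d-ribulose-1,5-bisphosphate	2.7.1.19		c08
d-gluconate	2-keto-d-gluconate	1.1.1.215		c09
5-amino-4-imidazolecarboxamide	phosphoribosyl-aica	2.4.2.7		c10
pyruvate	4-hydroxy-2-oxoglutarate	4.1.3.24		c11
guanine	gmp	2.4.2.10		c12
glycerate	tartrate	4.1.1.73		c13
bicarbonate	carboxyphosphate	6.3.5.5	b0032;b0033	c14
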