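substrate	product	ec
pyruvate	4-carboxy-4-hydroxy-2-oxoadipate	4.1.3.17
l-histidine	imidazol-5-yl-pyruvate	2.6.1.38
geranyl-diphosphate	geranyl-hydroxybenzoate	2.5.1.93
d-alanine	2-aminoacrylate	
phenylpyruvate	phenyllactate	1.1.1.237
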