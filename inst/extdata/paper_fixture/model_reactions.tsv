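substrate	product	ec	genes
cytosine	cmp	3.2.2.10	b2795
2-oxoglutarate	2-hydroxyglutarate	1.1.1.95	b2913
acetoacetyl-coa	acetoacetate	2.8.3.8;2.8.3.9	b2221;b2222;b1694
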