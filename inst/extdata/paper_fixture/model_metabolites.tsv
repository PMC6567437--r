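species
cytosine
2-oxoglutarate
bicarbonate
acetoacetyl-coa
l-glutamate
propanoyl-coa
d-ribulose-5-phosphate
d-gluconate
5-amino-4-imidazolecarboxamide
pyruvate
guanine
glycerate
l-histidine
geranyl-diphosphate
d-alanine
phenylpyruvate
l-serine
n-acetylornithine
n-carbamoyl-l-aspartate
cmp
2-hydroxyglutarate
acetoacetate
atp
adp
nad+
nadh
nadp+
nadph
coa
acetyl-coa
h2o
h+
co2
diphosphate
orthophosphate
thf
citrate
glyoxylate
oxaloacetate
4-hydroxybenzoate
3-cyano-l-alanine
ammonia
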