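macromolecule	percent
protein	52.8
lipid	8.4
carbohydrate	2.1
rna	22.6
dna	2.2
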