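amino_acid	molpct
Ala	12
Arg	5
Asx	10
Glx	12
Gly	10
His	2
Ile	4
Leu	10
Lys	5
Phe	4
Pro	5
Ser	5
Thr	5
Trp	NA
Tyr	3
Val	7
Cys	NA
Met	NA
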