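superfamily	class1
Gypsy	Retrotransposon
Copia	Retrotransposon
LINE_L1	Retrotransposon
SINE	Retrotransposon
hAT	DNA_transposon
Tc1_Mariner	DNA_transposon
Stowaway	DNA_transposon
Kiddo	DNA_transposon
Zator	DNA_transposon
Mutator	DNA_transposon
Helitron	DNA_transposon
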