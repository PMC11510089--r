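gene,receptor_class,product
ompC,OmpC,outer membrane porin C
ompA,OmpA,outer membrane protein A
wzzB,LPS-O-antigen,regulator of O-antigen chain length
wbbD,LPS-O-antigen,O-antigen synthesis galactosyltransferase
tarS,WTA-beta-GlcNAc,wall teichoic acid beta-GlcNAc transferase
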