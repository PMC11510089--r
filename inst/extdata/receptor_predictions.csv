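phage_id,predicted_receptors,prediction_note
303Ecol101PP,LPS-core-A;OmpC,LPS core and OmpC
308Ecol101PP,LPS-core-B;OmpC,LPS core and OmpC
310Ecol104PP,LPS-core-A;OmpA;PhoE,LPS core and OmpA and PhoE
348Ecol098PP,LPS-core-B;OmpC;OmpF;maltoporin,LPS core and OmpC or OmpF or maltoporin
241Ecol014PP,LPS;unknown-porin,Lipopolysaccharide (sugar) and unknown membrane protein
351Saur083PP,WTA-beta-GlcNAc,beta-O-N-acetylglucosamine of wall teichoic acid
355Saur083PP,WTA-beta-GlcNAc,beta-O-N-acetylglucosamine of wall teichoic acid
357Saur119PP,WTA-alpha-GlcNAc,putative alpha-O-N-acetylglucosamine of wall teichoic acid
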