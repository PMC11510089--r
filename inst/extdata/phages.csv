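phage_id,short_name,host_species,family,genus,main_receptors,support_receptors
241Ecol014PP,241,Escherichia coli,Vequintavirinae,Vequintavirus,LPS;unknown-porin,
303Ecol101PP,303,Escherichia coli,Straboviridae,Tequatrovirus,LPS-core-A;OmpC,
308Ecol101PP,308,Escherichia coli,Straboviridae,Mosigvirus,LPS-core-B;OmpC,
310Ecol104PP,310,Escherichia coli,Straboviridae,Tequatrovirus,LPS-core-A;OmpA;PhoE,
348Ecol098PP,348,Escherichia coli,Straboviridae,Mosigvirus,LPS-core-B;OmpC;OmpF;maltoporin,
351Saur083PP,351,Staphylococcus aureus,Rountreeviridae,Rosenblumvirus,WTA-beta-GlcNAc,unknown-oligosaccharide
355Saur083PP,355,Staphylococcus aureus,Herelleviridae,Kayvirus,WTA-beta-GlcNAc,unknown-oligosaccharide
357Saur119PP,357,Staphylococcus aureus,Herelleviridae,Kayvirus,WTA-alpha-GlcNAc,unknown-oligosaccharide
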