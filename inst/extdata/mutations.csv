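variant_id,species,nt_pos,aa_pos,effect,gene,product
119PP2018,Staphylococcus aureus,1177/1722,393/573,stop_gained,tarS,Poly(ribitol-phosphate) beta-N-acetylglucosaminyltransferase TarS
119PP2018,Staphylococcus aureus,,,intergenic,5SrRNA,5S ribosomal RNA (partial)
120PP2018,Staphylococcus aureus,1027/1722,343/573,stop_gained,tarS,Poly(ribitol-phosphate) beta-N-acetylglucosaminyltransferase TarS
120PP2018,Staphylococcus aureus,,,intergenic,5SrRNA,5S ribosomal RNA (partial)
121PP2018,Staphylococcus aureus,379/1722,127/573,missense,tarS,Poly(ribitol-phosphate) beta-N-acetylglucosaminyltransferase TarS
121PP2018,Staphylococcus aureus,,,intergenic,5SrRNA,5S ribosomal RNA (partial)
235PP2017,Escherichia coli,603/1104,201/367,frameshift,ompC,outer membrane porin C
1304PP2022,Escherichia coli,447/1104,149/367,frameshift,ompC,outer membrane porin C
1304PP2022,Escherichia coli,527/978,176/325,frameshift,wzzB,regulator of length of O-antigen component of lipopolysaccharide chains
1306PP2022,Escherichia coli,511/1104,171/367,stop_gained,ompC,outer membrane porin C
1306PP2022,Escherichia coli,453/978,151/325,stop_gained,wzzB,regulator of length of O-antigen component of lipopolysaccharide chains
265PP2018,Escherichia coli,97/1041,66/346,frameshift,ompA,outer membrane protein 3a
265PP2018,Escherichia coli,303/789,101/262,frameshift,wbbD,UDP-Gal:alpha-D-GlcNAc-diphosphoundecaprenol beta-1 3-galactosyltransferase
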