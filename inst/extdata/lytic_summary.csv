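phage_id,species,strong_pct,weak_pct,none_pct,is_overlap
241Ecol014PP,Escherichia coli,33.3,22.2,44.4,FALSE
303Ecol101PP,Escherichia coli,27.8,22.2,50.0,FALSE
308Ecol101PP,Escherichia coli,44.4,5.6,50.0,FALSE
310Ecol104PP,Escherichia coli,44.4,11.1,44.4,FALSE
348Ecol098PP,Escherichia coli,50.0,5.6,44.4,FALSE
all,Escherichia coli,83.3,0.0,16.7,TRUE
351Saur083PP,Staphylococcus aureus,40.0,20.0,40.0,FALSE
355Saur083PP,Staphylococcus aureus,86.7,6.7,6.7,FALSE
357Saur119PP,Staphylococcus aureus,26.7,13.3,60.0,FALSE
all,Staphylococcus aureus,93.3,6.7,0.0,TRUE
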