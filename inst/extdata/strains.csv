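species,strain_id,short_name,uwm_id,year
Escherichia coli,090PP2016,090,407,2016
Escherichia coli,091PP2016,091,408,2016
Escherichia coli,092PP2016,092,411,2016
Escherichia coli,093PP2016,093,412,2016
Escherichia coli,094PP2016,094,384,2016
Escherichia coli,095PP2016,095,230,2016
Escherichia coli,096PP2016,096,375,2016
Escherichia coli,097PP2016,097,381,2016
Escherichia coli,098PP2016,098,125,2016
Escherichia coli,099PP2016,099,513,2016
Escherichia coli,100PP2016,100,282,2016
Escherichia coli,101PP2016,101,124,2016
Escherichia coli,103PP2016,103,419,2016
Escherichia coli,104PP2016,104,418,2016
Escherichia coli,117PP2016,117,552,2016
Escherichia coli,118PP2016,118,551,2016
Escherichia coli,132PP2017,132,538,2017
Escherichia coli,133PP2017,133,574,2017
Staphylococcus aureus,058PP2016,058,377,2016
Staphylococcus aureus,059PP2016,059,360,2016
Staphylococcus aureus,060PP2016,060,342,2016
Staphylococcus aureus,062PP2016,062,312,2016
Staphylococcus aureus,063PP2016,063,322,2016
Staphylococcus aureus,067PP2016,067,390,2016
Staphylococcus aureus,069PP2016,069,522,2016
Staphylococcus aureus,075PP2016,075,476,2016
Staphylococcus aureus,076PP2016,076,227,2016
Staphylococcus aureus,079PP2016,079,294,2016
Staphylococcus aureus,080PP2016,080,165,2016
Staphylococcus aureus,082PP2016,082,228,2016
Staphylococcus aureus,083PP2016,083,536,2016
Staphylococcus aureus,090PP2016,090,544,2016
Staphylococcus aureus,091PP2016,091,556,2016
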