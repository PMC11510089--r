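month,species,titer_pfu_ml
0,Escherichia coli,2.16e8
0,Staphylococcus aureus,1.28e8
3,Escherichia coli,1.22e8
3,Staphylococcus aureus,6.82e7
6,Escherichia coli,1.25e8
6,Staphylococcus aureus,7.31e7
9,Escherichia coli,1.47e8
9,Staphylococcus aureus,8.30e7
12,Escherichia coli,9.16e7
12,Staphylococcus aureus,4.42e7
15,Escherichia coli,7.26e7
15,Staphylococcus aureus,2.97e7
18,Escherichia coli,1.12e8
18,Staphylococcus aureus,3.43e7
21,Escherichia coli,1.04e8
21,Staphylococcus aureus,3.09e7
24,Escherichia coli,1.04e8
24,Staphylococcus aureus,3.42e7
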