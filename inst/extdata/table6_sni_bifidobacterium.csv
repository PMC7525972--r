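source,target,sign
Acetanaerobacterium,Bifidobacterium,+
Akkermansia,Bifidobacterium,-
Clostridium_Candidatus_Arthromitus,Bifidobacterium,-
Lachnospiraceae_uncultured,Bifidobacterium,-
Ruminococcus,Bifidobacterium,-
Turicibacter,Bifidobacterium,-
Bifidobacterium,Acetanaerobacterium,+
Bifidobacterium,Barnesiella,+
Bifidobacterium,Candidate_division_TM7,+
Bifidobacterium,Erysipelotrichaceae_unclassified,+
Bifidobacterium,Eubacterium,+
Bifidobacterium,Mollicutes_RF9,+
Bifidobacterium,Ruminococcaceae_uncultured,+
Bifidobacterium,Allobaculum,-
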