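source,target,sign
Bacteroides,Staphylococcus,+
Clostridium_unclassified,Staphylococcus,+
Erysipelotrichaceae_Incertae_Sedis,Staphylococcus,+
Lachnospira,Staphylococcus,+
Parabacteroides,Staphylococcus,+
Ruminococcus,Staphylococcus,+
Turicibacter,Staphylococcus,+
Bacteroidales_unclassified,Staphylococcus,-
Candidate_division_TM7,Staphylococcus,-
Eubacterium,Staphylococcus,-
Lachnospiraceae_unclassified,Staphylococcus,-
Mollicutes_unclassified,Staphylococcus,-
Roseburia,Staphylococcus,-
Ruminococcaceae_Incertae_Sedis,Staphylococcus,-
Staphylococcus,Bacteria_unclassified,+
Staphylococcus,Clostridiales_unclassified,+
Staphylococcus,Desulfovibrio,+
Staphylococcus,Firmicutes_unclassified,+
Staphylococcus,Hydrogenoanaerobacterium,+
Staphylococcus,Lachnospiraceae_Incertae_Sedis,+
Staphylococcus,Lachnospiraceae_unclassified,+
Staphylococcus,Lachnospiraceae_uncultured,+
Staphylococcus,Mucispirillum,+
Staphylococcus,Oscillibacter,+
Staphylococcus,Oscillospira,+
Staphylococcus,Ruminococcaceae_Incertae_Sedis,+
Staphylococcus,Ruminococcaceae_unclassified,+
Staphylococcus,Akkermansia,-
Staphylococcus,Bacteroidales_S24-7,-
Staphylococcus,Lactobacillus,-
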