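source,target,sign
Clostridium_unclassified,Lactobacillus,+
Eubacterium,Lactobacillus,+
Firmicutes_unclassified,Lactobacillus,+
Parabacteroides,Lactobacillus,+
Parasutterella,Lactobacillus,+
Ruminococcus,Lactobacillus,+
Clostridia_unclassified,Lactobacillus,-
Lactobacillus,Desulfovibrio,+
Lactobacillus,Lachnospiraceae_uncultured,+
Lactobacillus,Oscillibacter,+
Lactobacillus,Ruminococcaceae_Incertae_Sedis,+
Lactobacillus,Ruminococcaceae_unclassified,+
Lactobacillus,Adlercreutzia,-
Lactobacillus,Bifidobacterium,-
Lactobacillus,Coprobacillus,-
Lactobacillus,Porphyromonadaceae_unclassified,-
Lactobacillus,Ruminococcus,-
Lactobacillus,Turicibacter,-
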