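source,target,sign
Hydrogenoanaerobacterium,Lactobacillus,+
Parasutterella,Lactobacillus,+
Staphylococcus,Lactobacillus,+
Bacteroidales_unclassified,Lactobacillus,-
Barnesiella,Lactobacillus,-
Lachnospiraceae_unclassified,Lactobacillus,-
Lactobacillus,Bacteria_unclassified,+
Lactobacillus,Clostridiales_unclassified,+
Lactobacillus,Desulfovibrio,+
Lactobacillus,Lachnospiraceae_uncultured,+
Lactobacillus,Parabacteroides,+
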