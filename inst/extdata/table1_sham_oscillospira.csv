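source,target,sign
Barnesiella,Oscillospira,+
Erysipelotrichaceae_unclassified,Oscillospira,+
Lactobacillus,Oscillospira,+
Mollicutes_RF9,Oscillospira,+
Mollicutes_unclassified,Oscillospira,+
Streptococcus,Oscillospira,+
Clostridiales_unclassified,Oscillospira,-
Firmicutes_unclassified,Oscillospira,-
Peptococcaceae,Oscillospira,-
Ruminococcus,Oscillospira,-
Ruminococcaceae_unclassified,Oscillospira,-
Oscillospira,Acetanaerobacterium,+
Oscillospira,Bacteroidales_unclassified,+
Oscillospira,Clostridium_Candidatus_Arthromitus,+
Oscillospira,Lachnospiraceae_unclassified,+
Oscillospira,Porphyromonadaceae_unclassified,+
Oscillospira,Ruminococcaceae_Incertae_Sedis,+
Oscillospira,Actinobacteria_unclassified,-
Oscillospira,Akkermansia,-
Oscillospira,Allobaculum,-
Oscillospira,Bacteroidales_S24-7,-
Oscillospira,Bifidobacterium,-
Oscillospira,Clostridium_unclassified,-
Oscillospira,Olsenella,-
Oscillospira,Parabacteroides,-
Oscillospira,Parasutterella,-
Oscillospira,Peptococcaceae_unclassified,-
Oscillospira,Ruminococcaceae_uncultured,-
Oscillospira,Ruminococcus,-
Oscillospira,Turicibacter,-
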