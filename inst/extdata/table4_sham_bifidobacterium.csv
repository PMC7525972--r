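source,target,sign
Adlercreutzia,Bifidobacterium,+
Turicibacter,Bifidobacterium,+
Lactobacillus,Bifidobacterium,-
Bacteroidales_S24-7,Bifidobacterium,-
Erysipelotrichaceae_unclassified,Bifidobacterium,-
Barnesiella,Bifidobacterium,-
Enterococcus,Bifidobacterium,-
Mollicutes_unclassified,Bifidobacterium,-
Oscillospira,Bifidobacterium,-
Bifidobacterium,Acinetobacter,+
Bifidobacterium,Ruminococcus,+
Bifidobacterium,Coriobacteriaceae_unclassified,-
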