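# Ordered classification rules for gut bacterial phyla learned from
# KEGG-pathway annotation counts over the top-ranked features.
(Genetic Information Processing: Folding, sorting, and degradation: Proteasome >= 1) => Actinobacteria
(Human Diseases: Drug resistance: Cationic antimicrobial peptide (CAMP) resistance <= 0) and (Genetic Information Processing: Folding, sorting, and degradation: Protein processing in endoplasmic reticulum >= 2) => Actinobacteria
(Cellular Processes: Transport and catabolism: Peroxisome <= 0) and (Genetic Information Processing: Folding, sorting, and degradation: Protein processing in endoplasmic reticulum >= 2) and (Human Diseases: Drug resistance: Cationic antimicrobial peptide (CAMP) resistance <= 1) => Actinobacteria
(Organismal Systems: Digestive system: Protein digestion and absorption >= 1) => Bacteroidetes
others => Firmicutes
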