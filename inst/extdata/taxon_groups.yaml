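guilds:
  risk:
  - Eggerthella
  - Anaerotruncus
  - Klebsiella
  butyrate:
  - Butyricimonas
  - Odoribacter
  - Anaerostipes
  - Anaerobutyricum
  - Agathobacter
  - Butyrivibrio
  - Coprococcus
  - Roseburia
  - Shuttleworthia
  - Butyricicoccus
  - Oscillibacter
  - Faecalibacterium
  - Flavonifractor
  - Pseudoflavonifractor
  - Subdoligranulum
  - Subdoligranulum variabile
  - Eubacterium ventriosum
  lactate:
  - Bifidobacterium
  - Lactobacillus
  - Streptococcus
  - Enterococcus
  - Leuconostoc
  - Lactococcus
  - Pediococcus
phylum:
  Anaerostipes: Firmicutes
  Anaerobutyricum: Firmicutes
  Agathobacter: Firmicutes
  Butyrivibrio: Firmicutes
  Coprococcus: Firmicutes
  Roseburia: Firmicutes
  Shuttleworthia: Firmicutes
  Butyricicoccus: Firmicutes
  Oscillibacter: Firmicutes
  Faecalibacterium: Firmicutes
  Flavonifractor: Firmicutes
  Pseudoflavonifractor: Firmicutes
  Subdoligranulum: Firmicutes
  Subdoligranulum variabile: Firmicutes
  Eubacterium ventriosum: Firmicutes
  Anaerotruncus: Firmicutes
  Lactobacillus: Firmicutes
  Streptococcus: Firmicutes
  Enterococcus: Firmicutes
  Leuconostoc: Firmicutes
  Lactococcus: Firmicutes
  Pediococcus: Firmicutes
  Blautia: Firmicutes
  Ruminococcus: Firmicutes
  Dorea: Firmicutes
  Veillonella: Firmicutes
  Dialister: Firmicutes
  Bacteroides: Bacteroidetes
  Prevotella: Bacteroidetes
  Alistipes: Bacteroidetes
  Parabacteroides: Bacteroidetes
  Odoribacter: Bacteroidetes
  Butyricimonas: Bacteroidetes
  Bifidobacterium: Actinobacteria
  Eggerthella: Actinobacteria
  Collinsella: Actinobacteria
  Klebsiella: Proteobacteria
  Escherichia: Proteobacteria
  Sutterella: Proteobacteria
  Bilophila: Proteobacteria
  Akkermansia: Verrucomicrobia
  Fusobacterium: Fusobacteria
gram:
  Anaerostipes: positive
  Anaerobutyricum: positive
  Agathobacter: positive
  Butyrivibrio: positive
  Coprococcus: positive
  Roseburia: positive
  Shuttleworthia: positive
  Butyricicoccus: positive
  Oscillibacter: positive
  Faecalibacterium: positive
  Flavonifractor: positive
  Pseudoflavonifractor: positive
  Subdoligranulum: positive
  Subdoligranulum variabile: positive
  Eubacterium ventriosum: positive
  Anaerotruncus: positive
  Lactobacillus: positive
  Streptococcus: positive
  Enterococcus: positive
  Leuconostoc: positive
  Lactococcus: positive
  Pediococcus: positive
  Blautia: positive
  Ruminococcus: positive
  Dorea: positive
  Veillonella: negative
  Dialister: negative
  Bacteroides: negative
  Prevotella: negative
  Alistipes: negative
  Parabacteroides: negative
  Odoribacter: negative
  Butyricimonas: negative
  Bifidobacterium: positive
  Eggerthella: positive
  Collinsella: positive
  Klebsiella: negative
  Escherichia: negative
  Sutterella: negative
  Bilophila: negative
  Akkermansia: negative
  Fusobacterium: negative
pathogens:
  obligate:
  - Brucella ovis
  - Brucella pinnipedialis
  - Salmonella enterica
  - Campylobacter jejuni
  - Listeria monocytogenes
  - Helicobacter pylori
  - Neisseria gonorrhoeae
  - Neisseria meningitidis
  - Streptococcus pyogenes
  - Haemophilus influenzae
  facultative:
  - Acinetobacter baumannii
  - Klebsiella pneumoniae
  - Pseudomonas aeruginosa
  - Staphylococcus aureus
  - Clostridium perfringens
  - Enterococcus faecalis
  - Enterococcus faecium
  - Escherichia coli
  - Mycobacterium avium
  - Mycobacterium abscessus
  - Streptococcus pneumoniae
mycotoxin_food_weights:
  grains: 0.5
  dairy: 0.3
  nuts: 0.2
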