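name	group
Ciliophora	Ciliophora
Dinophyceae	Dinophyceae
Alveolata	other Alveolata
Amoebozoa	Amoebozoa
Euglenozoa	Euglenozoa
Fungi	Fungi
Metazoa	Metazoa
Opisthokonta	other Opisthokonta
Chlorophyta	Plantae
Rhodophyta	Plantae
Glaucophyta	Plantae
Cercozoa	Cercozoa
Rhizaria	other Rhizaria
Foraminifera	other Rhizaria
Radiolaria	other Rhizaria
Bacillariophyta	Bacillariophyta
Chrysophyceae	Chrysophyceae
Labyrinthulea	Labyrinthulea
Stramenopiles	other Stramenopiles
Cryptophyta	CCTH
Haptophyta	CCTH
Telonemia	CCTH
Centroheliozoa	CCTH
Apusozoa	other Eukarya
Picobiliphyta	other Eukarya
Katablepharidophyta	other Eukarya
Heterolobosea	other Eukarya
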