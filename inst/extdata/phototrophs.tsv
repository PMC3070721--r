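name
Chlorophyta
Rhodophyta
Glaucophyta
Haptophyta
Picobiliphyta
Radiolaria
Bacillariophyta
Bolidophyceae
Dictyochophyceae
Pelagophyceae
Phaeophyceae
Phaeothamniophyceae
Pinguiophyceae
Raphidophyceae
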