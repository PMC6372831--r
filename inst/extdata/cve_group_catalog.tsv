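group	clade	genes	n_seqs	n_species	tentative	single_origin_duplicated
Eptatretus	Agnatha	rep	7	1	TRUE	FALSE
Anguilla	Fish	rep	1	1	FALSE	FALSE
Characiformes	Fish	rep	1	1	FALSE	FALSE
Clupeiformes	Fish	rep	1	1	FALSE	FALSE
Cypriniformes	Fish	rep+cap	6	2	FALSE	FALSE
Cyprinodontiformes	Fish	rep	4	1	FALSE	FALSE
Perciformes	Fish	rep	8	3	FALSE	FALSE
Salmoniformes	Fish	rep	3	1	FALSE	FALSE
Anura	Amphibia	rep	2	2	FALSE	FALSE
Viperidae	Reptilia	rep+cap	16	6	FALSE	FALSE
Tinamou	Aves	rep+cap	2	1	FALSE	FALSE
Psittaciformes	Aves	rep+cap	4	3	FALSE	FALSE
Passeriformes	Aves	rep	7	5	FALSE	FALSE
Egretta	Aves	rep	1	1	FALSE	FALSE
Gallirallus	Aves	rep	1	1	FALSE	FALSE
Picoides	Aves	rep	1	1	FALSE	FALSE
Chrysochloris	Mammalia	rep,cap	3	1	FALSE	FALSE
Carnivora	Mammalia	rep	101	13	FALSE	TRUE
Mus.caroli	Mammalia	rep	1	1	FALSE	FALSE
Heterocephalus	Mammalia	rep	1	1	FALSE	FALSE
Phascolarctos	Mammalia	rep	1	1	FALSE	FALSE
Sarcophilus	Mammalia	rep	1	1	FALSE	FALSE
Monodelphis	Mammalia	rep	1	1	FALSE	FALSE
Galeopterus	Mammalia	rep	2	1	FALSE	FALSE
Manis	Mammalia	rep	1	1	FALSE	FALSE
Choloepus	Mammalia	cap	2	1	FALSE	FALSE
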