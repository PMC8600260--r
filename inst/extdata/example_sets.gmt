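ribosome	cytosolic ribosome subunits	g00001	g00002	g00003	g00004	g00005	g00006
mapk_cascade	MAP kinase signalling	g00010	g00011	g00012	g00013
glutathione	glutathione metabolism	g00020	g00021	g00022
ion_channels	K and Ca channel subunits	g00030	g00031	g00032	g00033	g00034
dna_repair	mismatch repair components	g00040	g00041
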