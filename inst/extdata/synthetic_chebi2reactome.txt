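10	R-HSA-0001	https://reactome.org/content/detail/R-HSA-0001	Alpha oxidation (synthetic)	TAS	Homo sapiens
11	R-HSA-0001	https://reactome.org/content/detail/R-HSA-0001	Alpha oxidation (synthetic)	TAS	Homo sapiens
12	R-HSA-0001	https://reactome.org/content/detail/R-HSA-0001	Alpha oxidation (synthetic)	TAS	Homo sapiens
12	R-HSA-0002	https://reactome.org/content/detail/R-HSA-0002	Beta pathway (synthetic)	TAS	Homo sapiens
13	R-HSA-0002	https://reactome.org/content/detail/R-HSA-0002	Beta pathway (synthetic)	TAS	Homo sapiens
10	R-MMU-0001	https://reactome.org/content/detail/R-MMU-0001	Alpha oxidation (synthetic)	TAS	Mus musculus
11	R-MMU-0001	https://reactome.org/content/detail/R-MMU-0001	Alpha oxidation (synthetic)	TAS	Mus musculus
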