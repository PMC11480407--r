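gene_id	log2fc	pvalue	fdr	label
fimC	1.88	1e-05	0.01	protein folding
fimF	1.86	1e-05	0.01	pilus assembly
fimI	1.84	1e-05	0.01	pilus assembly
fimD	1.83	1e-05	0.01	pilus assembly
fimG	1.52	1e-05	0.01	pilus assembly
fimZ	1.71	1e-05	0.01	transcription regulation (pilus assembly)
rrlG	1.71	1e-05	0.01	translation
rrlC	1.63	1e-05	0.01	translation
rrlB	1.58	1e-05	0.01	translation
rrlA	1.54	1e-05	0.01	translation
flgB	-2.26	1e-05	0.01	bacterial-type flagellum-dependent cell motility
fliA	-2.05	1e-05	0.01	transcription initiation
valU	0.42	1e-06	1e-05	tRNA
valX	0.38	1e-06	1e-05	tRNA
valY	0.40	1e-06	1e-05	tRNA
valT	0.35	1e-06	1e-05	tRNA
valZ	0.33	1e-06	1e-05	tRNA
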