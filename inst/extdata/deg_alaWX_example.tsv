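gene_id	log2fc	pvalue	fdr	label
fimC	3.25	1e-05	0.01	protein folding
fimF	2.44	1e-05	0.01	pilus assembly
fimI	2.37	1e-05	0.01	pilus assembly
fimD	2.62	1e-05	0.01	pilus assembly
fimG	2.34	1e-05	0.01	pilus assembly
fimZ	2.12	1e-05	0.01	transcription regulation (pilus assembly)
rrlG	2.76	1e-05	0.01	translation
rrlC	2.16	1e-05	0.01	translation
rrlB	2.17	1e-05	0.01	translation
rrlA	1.93	1e-05	0.01	translation
flgB	-2.13	1e-05	0.01	bacterial-type flagellum-dependent cell motility
fliA	-1.89	1e-05	0.01	transcription initiation
alaT	-0.35	1e-06	1e-05	tRNA
alaU	-0.32	1e-06	1e-05	tRNA
alaV	-0.30	1e-06	1e-05	tRNA
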