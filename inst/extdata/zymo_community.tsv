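species	dna_percent	genome_mb	volume_um3	signature_tsm
Pseudomonas aeruginosa	12	6.58	0.49	271.3
Escherichia coli	12	5.17	0.65	884.9
Salmonella enterica	12	4.78	0.96	670.2
Lactobacillus fermentum	12	1.99	1.41	3373
Enterococcus faecalis	12	3.03	0.52	1002.8
Staphylococcus aureus	12	2.85	0.90	2380.7
Listeria monocytogenes	12	2.98	0.27	1163.2
Bacillus subtilis	12	4.13	2.69	2946.1
Saccharomyces cerevisiae	2	12.13	33.51	959.7
Cryptococcus neoformans	2	19.05	33.51	267.9
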