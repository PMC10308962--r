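read001		Root	rootrank	1.0	Bacteria	domain	1.0	Proteobacteria	phylum	0.99	Gammaproteobacteria	class	0.98	Enterobacterales	order	0.97	Enterobacteriaceae	family	0.96	Escherichia/Shigella	genus	0.95
read002		Root	rootrank	1.0	Bacteria	domain	1.0	Acidobacteria	phylum	0.97	Acidobacteria_Gp6	class	0.93	Gp6	genus	0.88
read003		Root	rootrank	1.0	Bacteria	domain	1.0	Cyanobacteria/Chloroplast	phylum	0.99	Cyanobacteria	class	0.95
read004		Root	rootrank	1.0	Bacteria	domain	1.0
read005		Root	rootrank	1.0	Bacteria	domain	1.0	Cyanobacteria/Chloroplast	phylum	0.99	Chloroplast	class	0.97
read006		Root	rootrank	1.0	Archaea	domain	1.0	Euryarchaeota	phylum	0.98	Methanococci	class	0.95	Methanococcales	order	0.94	Methanococcaceae	family	0.92	Methanococcus	genus	0.91
read007		Root	rootrank	1.0	Bacteria	domain	1.0	Firmicutes	phylum	0.99	Clostridia	class	0.98	Clostridiales	order	0.97
read008		Root	rootrank	1.0	Bacteria	domain	1.0	Proteobacteria	phylum	0.99	Gammaproteobacteria	class	0.98	Enterobacterales	order	0.97	Enterobacteriaceae	family	0.96	Escherichia/Shigella	genus	0.93
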