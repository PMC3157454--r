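gene_id	name	maternal_reads	paternal_reads
AT1G57800	VIM5	142	1898
AT1G57820	VIM1	181	302
AT4G08590	VIM6	99	147
AT1G17770	SUVH7	10	32
AT4G13460	SUVH9	86	130
AT2G21450	CHR34	13	43
AT1G63020	PolIVa	168	207
AT1G59890	SNL5	14	28
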