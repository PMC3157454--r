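gene_id	name	colxler_col	colxler_ler	lerxcol_col	lerxcol_ler	passes_all
AT2G32370	HDG3	79	190	303	96	TRUE
AT2G35670	FIS2	13	0	6	16	FALSE
AT3G03260	HDG8	2	6	12	8	FALSE
AT4G00540	MYB3R2	129	0	9	77	TRUE
AT4G25530	FWA	5	0	0	0	FALSE
AT5G17320	HDG9	29	1	3	117	TRUE
AT5G54650	FH5	54	12	14	43	FALSE
AT5G62110	AT5G62110	1	3	2	0	FALSE
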