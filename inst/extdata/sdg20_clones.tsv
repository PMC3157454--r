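sample	cross	col_clones	ler_clones
original	ColxLer	15	11
original	LerxCol	17	7
independent	ColxLer	18	11
independent	LerxCol	14	14
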