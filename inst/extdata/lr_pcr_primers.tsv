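name	sequence	coverage	size_kb
ABO1longF	GCTTCCAGCTTTTGGCTATG	5'-UTR~Intron 1	12.8
ABO1longR	GTGACCACGGAGCGATTTAT	5'-UTR~Intron 1	12.8
ABOe27longF	GGATTAACAATGGCGTGCTT	Intron 1~3'-UTR	8.7
ABOe27longR	GGACGGACAAAGGAAACAGA	Intron 1~3'-UTR	8.7
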