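species	abbrev	sequence_printed
Agaricus bisporus	Ab	TTTCAGAGGAGCTGACCCCAAGTAA
Alternaria alternata	Aa	TTTGCTGATAGAGAGTGCGACTTGT
Apiotrichum laibachii	Al	TTTGAACGCAACTTGCGCTCTCTGG
Aspergillus flavus	Af	TTTCGGAGTTCACCGGCATCAGTGC
Auricularia heimuer	Ah	TTTCAAGACGAGCCGATTACCGGCA
Botrytis cinerea	Bc	TTTAGAGCCTGCCATTACTGACATA
Fusarium oxysporum	Fo	TTTGCTGCGTTCTTCATCGATGCCA
Ganoderma lucidum	Gl	TTTGTAGGCTTGGACTTGGAGGCTT
Lentinula edodes	Le	TTTCTCCAATGAATAGAACAGATTGA
Ophiocordyceps sinensis	Os	TTTGGGAGTGGTGAC TCGATAATGA
Rhodotorula mucilaginosa	Rm	TTTACGGTCTAGCTCGTTCGTAATG
Saccharomyces cerevisiae	Sc	TTTAAGAACATTGTTCGCCTAGACG
Wolfiporia cocos	Wc	TTTCTAGGGTTCCCGTTCAACGGCG
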