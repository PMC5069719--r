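# mtDNA control-region haplotype counts, north and south populations
Haplotypes	North	South	Total
H1	5	26	31
H2		3	3
H3	5		5
H4	6		6
H5	1		1
H6	3		3
H7		6	6
H8		1	1
H9		1	1
H10	2		2
H11		1	1
H12		1	1
H13	2		2
H14		1	1
Samples	24	40	64
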