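BC12	TTGACGCA
BC23	GAACTGTC
BC31	CATGTACG
BC49	ACCGTTAG
BC56	GTCAAGGT
BC62	TGGCACTT
BC74	CCGTTAGC
BC88	AGTTCCAG
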