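EZR-1	TTCAGATTACAGGCATCGTA
EZR-2	GATTACAGGCATCGTAGCCT
PPIB-1	CTGGAGAGCACCAAGATTGC
PPIB-2	GGCACTGGAGAGCACCAAGA
DPP4-1	ACGTTGCCAATGGTCAGTAC
DPP4-2	TGCCATAGTTCGGAACTGGA
CD81-1	GTTCACGGATCCTGAATCGT
CD81-2	CAAGTCCTTGGCATGACGAT
NTC-1	ATCGGCTAAGTTCACCGGTA
NTC-2	GCTAACGGTTAGCATCCATG
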