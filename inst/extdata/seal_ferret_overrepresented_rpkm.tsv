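gene	seal_rpkm	ferret_rpkm	printed_fold
S100B	1860.3	49.0	37.98
OGN	288.0	23.7	12.14
NEIL2	51.1	5.1	10.11
HSD17B11	81.3	12.6	6.46
B2M	242.1	38.7	6.26
CYP4V2	86.2	14.3	6.05
PON2	95.9	17.3	5.54
BGN	41.1	7.7	5.35
MSN	60.4	11.3	5.33
TM4SF1	33.4	6.3	5.31
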