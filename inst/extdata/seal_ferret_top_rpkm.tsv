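gene	seal_rpkm	ferret_rpkm	printed_fold	table
CLU	3104.57	777.62	3.99	A
PTGDS	2213.95	1451.49	1.53	AB
S100B	1860.29	48.98	37.98	A
GAPDH	1413.17	3728.00	-2.64	AB
GDPD2	1334.93	277.95	4.80	A
GLUL	1046.64	768.49	1.36	A
CALM2	1002.24	1805.51	-1.80	AB
SPARCL1	938.95	536.88	1.75	A
ALDOC	918.67	906.26	1.01	A
PSAP	883.57	913.66	-1.03	A
MTCO2	245.64	2266.01	-9.22	B
LOC101679695	98.39	1824.67	-18.55	B
CALM1	480.64	1802.73	-3.75	B
ATP5B	541.42	1166.96	-2.16	B
LDHB	453.40	1127.78	-2.49	B
MDH1	544.42	1055.62	-1.94	B
RPL26	289.61	1040.08	-3.59	B
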