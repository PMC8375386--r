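city	summer_temperature	winter_temperature	summer_humidity	winter_humidity	coastal	urbanization
ARN	0	0	1	1	1	0
BCN	1	1	1	0	1	1
BER	1	0	1	1	0	1
DEN	1	0	0	0	0	0
DOH	2	2	0	0	1	0
FAI	0	0	1	1	0	0
HKG	2	2	2	1	1	0
ICN	1	0	1	0	0	1
IEV	1	0	1	1	0	1
ILR	2	3	2	0	0	0
KUL	2	3	2	1	0	1
LCY	0	1	1	1	0	1
LIS	1	1	1	1	1	0
NYC	1	0	1	1	1	1
OFF	2	3	2	0	0	1
SAO	1	2	1	1	0	1
SCL	0	1	0	0	0	1
SDJ	1	0	2	1	1	1
SFO	0	1	1	1	1	1
SGP	2	3	2	1	1	1
TPE	2	2	1	1	1	1
TYO	2	1	1	0	1	1
ZRH	0	0	1	1	1	1
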