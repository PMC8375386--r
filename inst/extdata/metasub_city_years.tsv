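city_name	city	year
Stockholm	ARN	2017
Barcelona	BCN	2016
Berlin	BER	2016
Denver	DEN	2016
Denver	DEN	2017
Doha	DOH	2016
Doha	DOH	2017
Fairbanks	FAI	2016
Hong Kong	HKG	2017
Seoul	ICN	2017
Kiev	IEV	2017
Ilorin	ILR	2016
Ilorin	ILR	2017
Kuala Lumpur	KUL	2017
London	LCY	2017
Lisbon	LIS	2016
New York	NYC	2016
New York	NYC	2017
Offa	OFF	2016
Sao Paulo	SAO	2017
Santiago	SCL	2016
Sendai	SDJ	2017
San Francisco	SFO	2017
Singapore	SGP	2017
Taipei	TPE	2017
Tokyo	TYO	2016
Tokyo	TYO	2017
Zurich	ZRH	2017
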