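country	region
US	North America
CA	North America
MX	North America
BR	South America
AR	South America
CO	South America
GB	Europe
DE	Europe
FR	Europe
IT	Europe
ES	Europe
NL	Europe
PL	Europe
SE	Europe
CH	Europe
CN	Asia
JP	Asia
KR	Asia
IN	Asia
TH	Asia
IL	Asia
AU	Oceania
NZ	Oceania
ZA	Africa
EG	Africa
NG	Africa
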