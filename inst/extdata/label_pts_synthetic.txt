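Diarrhoea
Nausea
Vomiting
Rash
Palmar-plantar erythrodysaesthesia syndrome
Dry skin
Paronychia
Dermatitis acneiform
Fatigue
Decreased appetite
Stomatitis
Dyspepsia
Neutropenia
Hepatotoxicity
Insomnia
Headache
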