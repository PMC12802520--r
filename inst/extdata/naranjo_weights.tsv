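question	yes	no	unknown
previous_conclusive_reports	1	0	0
event_after_drug	2	-1	0
improvement_on_withdrawal	1	0	0
reappearance_on_rechallenge	2	-1	0
alternative_causes	-1	2	0
placebo_reaction	-1	1	0
toxic_drug_concentration	1	0	0
dose_response	1	0	0
past_similar_reaction	1	0	0
objective_confirmation	1	0	0
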