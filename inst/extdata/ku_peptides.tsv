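peptide	sequence	printed_span	parent_start	parent_end	synthesized_sequence	reported_mass_Da	reported_contacts	reported_fraction_pct	reported_occupancy	reported_solubility	note
Ku1	ITKEEASGSSVTAEEAKKFLAP	586-707	686	707	ITKEEASGSSVTAEEAKKFLAG	2253	18	81.82	200	good	printed start 586 inconsistent with 22-aa sequence, corrected to 686; terminal P replaced by G for synthesis, reported mass is for the G variant
Ku2	RVLVKQKKASFEEASNQLINHIEQFL	599-624	599	624	RVLVKQKKASFEEASNQLINHIEQFL	3071	22	84.62	192	good
Ku3	EIVVQDGITLITKEEASGSSVTAEEAKK	676-703	676	703	EIVVQDGITLITKEEASGSSVTAEEAKK	2933	18	64.29	179	good
Ku4	ASFEEASNQLINHIEQFLDTNETPYFMKSI	607-635	607	636	ASFEEASNQLINHIEQFLDTNETPYFMKSI	3518	18	60.00	145	poor	printed end 635 inconsistent with 30-aa sequence, corrected to 636
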