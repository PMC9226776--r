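library_id	sample	vector	clones	mean_insert_kb	confirmed_hits
compost55_pFLD	compost55	plasmid	675200	5.3	156
compost55_pCRXL	compost55	plasmid	234912	5.6	43
compost76_pFLD	compost76	plasmid	281281	6.0	37
compost76_pCRXL	compost76	plasmid	140747	6.2	14
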