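species	genome_size_1c_pg	ploidy	target_copies_per_haploid	class
Origanum vulgare	1.05	2	1	ingredient
Origanum onites	1.00	2	1	ingredient
Origanum majorana	1.10	2	1	adulterant
Olea europaea	1.46	2	1	adulterant
Myrtus communis	0.45	2	1	adulterant
Cistus spp.	1.10	2	1	adulterant
Convolvulus arvensis	0.75	2	1	contaminant
Chenopodium album	1.60	6	1	contaminant
Thymus spp.	0.60	2	1	contaminant
Corylus spp.	0.48	2	1	contaminant
Rhus coriaria	0.70	2	1	contaminant
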