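taxon	kingdom	reads
Origanum vulgare	Plantae	1126
Origanum onites	Plantae	109
Origanum spp.	Plantae	564
Thymus spp.	Plantae	345
Convolvulus spp.	Plantae	3771
Cistus spp.	Plantae	606
Myrtus communis	Plantae	25
Olea europaea	Plantae	33
Corylus spp.	Plantae	531
Rhus coriaria	Plantae	0
Amaranthus spp.	Plantae	1105
Camonea/Ipomoea spp.	Plantae	505
Calystegia spp.	Plantae	2974
Chenopodium spp.	Plantae	1306
O. majorana	Plantae	4
Mentha x piperita	Plantae	133
Salvia/perilla spp.	Plantae	133
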