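# Andean Biotic Index (ABI) family tolerance scores, transcribed from the
# published ABI tolerance list (external provenance; editable). Families kept
# at a higher taxonomic rank in that list (Oligochaeta, Turbellaria,
# Erpobdellidae's order) carry no family-level score here ("-").
family	score_abi
Acari	4
Erpobdellidae	-
Lumbricidae	-
Tubificidae	-
Chironomidae	2
Limoniidae	4
Muscidae	2
Scirtidae	5
Ceratopogonidae	4
Glossiphoniidae	3
Dugesiidae	-
Elmidae	5
Hyallelidae	6
Baetidae	4
Simuliidae	5
Hydroptilidae	6
Leptoceridae	8
Limnephilidae	7
Hydrobioscidae	8
Gripopterygidae	10
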