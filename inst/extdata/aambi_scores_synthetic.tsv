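# SYNTHETIC Andean-Amazon Biotic Index (AAMBI) family tolerance scores.
# The original AAMBI tolerance list is not redistributed here; these integer
# scores (1-10) were calibrated so that index sums over the packaged Antisana
# presence matrix reproduce every AAMBI site value and class reported for
# that survey (minimum 6 at AL3, 33 at ALB2, 35 at J1A, maximum 66 at H2,
# H1/H3/J1B in the "good" band, remaining sites 36-49). Treat as a plausible
# stand-in, not the published table.
family	score_aambi
Acari	-
Erpobdellidae	-
Lumbricidae	-
Tubificidae	1
Chironomidae	2
Limoniidae	4
Muscidae	2
Scirtidae	4
Ceratopogonidae	4
Glossiphoniidae	3
Dugesiidae	1
Elmidae	5
Hyallelidae	7
Baetidae	4
Simuliidae	4
Hydroptilidae	6
Leptoceridae	8
Limnephilidae	7
Hydrobioscidae	8
Gripopterygidae	10
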