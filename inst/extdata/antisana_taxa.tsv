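family	score_bmwp_col	ffg
Acari	-	PR
Erpobdellidae	-	PR
Lumbricidae	-	CG
Tubificidae	1	CG
Chironomidae	2	CG
Limoniidae	3	CG
Muscidae	4	PR
Scirtidae	4	CG
Ceratopogonidae	5	PR
Glossiphoniidae	5	PR
Dugesiidae	6	PA
Elmidae	6	SC
Hyallelidae	7	SH
Baetidae	7	SC
Simuliidae	7	CF
Hydroptilidae	8	SC
Leptoceridae	8	CG
Limnephilidae	8	SH
Hydrobioscidae	9	PR
Gripopterygidae	10	SC
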