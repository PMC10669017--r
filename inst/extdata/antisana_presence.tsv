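family	AL3	A1	AL1	AL2	ALB1	ALB2	H5	H6	J1A	J1C	H1	H2	H3	H4	J1B
Acari					p	p
Erpobdellidae										p
Lumbricidae		p					p		p
Tubificidae											p		p	p	p
Chironomidae	p	p	p	p				p		p	p	p		p	p
Limoniidae					p
Muscidae			p				p								p
Scirtidae		p		p	p	p		p	p	p	p	p	p		p
Ceratopogonidae			p	p	p		p
Glossiphoniidae				p			p			p			p		p
Dugesiidae		p	p	p		p	p	p	p	p	p	p	p	p	p
Elmidae		p	p	p	p	p	p			p	p	p	p	p	p
Hyallelidae		p	p	p	p	p	p	p	p	p	p	p	p	p	p
Baetidae	p	p	p	p	p	p	p	p	p	p	p	p	p	p	p
Simuliidae			p			p		p	p	p	p	p	p	p	p
Hydroptilidae												p
Leptoceridae		p				p			p	p	p	p	p	p	p
Limnephilidae		p		p			p	p	p	p	p	p	p	p	p
Hydrobioscidae			p		p		p				p	p		p	p
Gripopterygidae		p						p			p	p	p
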