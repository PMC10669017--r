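# Alternate family spellings mapped onto the canonical spellings used by the
# packaged tables (the survey's spellings are kept canonical).
synonym	canonical
Hyalellidae	Hyallelidae
Hydrobiosidae	Hydrobioscidae
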