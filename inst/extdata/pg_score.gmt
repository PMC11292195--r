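PG_SCORE	11-protein proteoglycan signature (10 members named in the source text; HAPLN1 reconstructed for the remaining figure-only member)	ACAN	VCAN	HSPG2	BGN	DCN	ASPN	FMOD	LUM	PRELP	OGN	HAPLN1
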