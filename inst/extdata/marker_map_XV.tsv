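# Scored chromosome XV markers of the EAY1108/1112 background (positions kb,
# cumulative physical distances between adjacent marker genes).
chromosome	marker	position_kb
XV	URA3	0
XV	LEU2	136
XV	LYS2	179
XV	ADE2	238
XV	HIS3	395
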