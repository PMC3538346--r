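# Scored markers of the NHY942/943 background. Positions are cumulative
# physical distances (kb) between adjacent marker genes, anchored at 0.
chromosome	marker	position_kb
III	HIS4	0
III	LEU2	23
III	CEN3	45
III	MAT	135
VII	LYS5	0
VII	MET13	56
VII	CYH2	92
VII	TRP5	227
VIII	CEN8	0
VIII	THR1	54
VIII	CUP1	106
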