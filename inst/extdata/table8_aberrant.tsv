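# Aberrant (3:1 or 1:3) marker segregation, percent of four-spore-viable
# tetrads, per marker; '(total)' rows are the printed per-chromosome totals.
genotype	chromosome	marker	n_tetrads	percent_aberrant
wild type	III	HIS4	572	2.1
wild type	III	LEU2	572	0.3
wild type	III	ADE2	572	0.2
wild type	III	MATa	572	0.2
wild type	III	(total)	572	2.8
mlh3d	III	HIS4	306	0.7
mlh3d	III	LEU2	306	0.7
mlh3d	III	ADE2	306	0.3
mlh3d	III	MATa	306	0.0
mlh3d	III	(total)	306	1.7
mms4d	III	HIS4	32	9.4
mms4d	III	LEU2	32	6.3
mms4d	III	ADE2	32	3.1
mms4d	III	MATa	32	3.1
mms4d	III	(total)	32	21.9
mlh3d mms4d	III	HIS4	170	4.1
mlh3d mms4d	III	LEU2	170	0.6
mlh3d mms4d	III	ADE2	170	0.0
mlh3d mms4d	III	MATa	170	1.2
mlh3d mms4d	III	(total)	170	5.9
wild type	VII	LYS5	572	1.6
wild type	VII	MET13	572	2.4
wild type	VII	CYH2	572	0.3
wild type	VII	TRP5	572	0.7
wild type	VII	(total)	572	5.0
mlh3d	VII	LYS5	306	0.7
mlh3d	VII	MET13	306	2.0
mlh3d	VII	CYH2	306	0.0
mlh3d	VII	TRP5	306	0.0
mlh3d	VII	(total)	306	2.7
mms4d	VII	LYS5	32	9.4
mms4d	VII	MET13	32	0.0
mms4d	VII	CYH2	32	6.3
mms4d	VII	TRP5	32	0.0
mms4d	VII	(total)	32	15.7
mlh3d mms4d	VII	LYS5	170	1.2
mlh3d mms4d	VII	MET13	170	2.4
mlh3d mms4d	VII	CYH2	170	0.0
mlh3d mms4d	VII	TRP5	170	1.2
mlh3d mms4d	VII	(total)	170	4.8
wild type	VIII	URA3	572	0.2
wild type	VIII	THR1	572	5.1
wild type	VIII	CUP1	572	0.7
wild type	VIII	(total)	572	6.0
mlh3d	VIII	URA3	306	0.0
mlh3d	VIII	THR1	306	3.3
mlh3d	VIII	CUP1	306	0.0
mlh3d	VIII	(total)	306	3.3
mms4d	VIII	URA3	32	0.0
mms4d	VIII	THR1	32	6.3
mms4d	VIII	CUP1	32	9.4
mms4d	VIII	(total)	32	15.7
mlh3d mms4d	VIII	URA3	170	0.6
mlh3d mms4d	VIII	THR1	170	4.7
mlh3d mms4d	VIII	CUP1	170	0.6
mlh3d mms4d	VIII	(total)	170	5.9
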