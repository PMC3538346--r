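# Spore viability (%) and cumulative map distances (cM) per chromosome.
# source: this_study rows are the dissections tallied here; 'ref' marks the
# externally published 272-tetrad mms4d dataset; 'fold' rows hold the printed
# fold decrease in crossing over of mlh3d mms4d relative to wild type.
genotype	source	spore_viability_pct	n_tetrads	chromosome	cumulative_cM
wild type	this_study	91.0	572	III	34.9
wild type	this_study	91.0	572	VII	68.7
wild type	this_study	91.0	572	VIII	46.2
wild type	this_study	91.0	572	XV	96.1
mlh3d	this_study	79.0	306	III	29.3
mlh3d	this_study	79.0	306	VII	32.4
mlh3d	this_study	79.0	306	VIII	20.3
mlh3d	this_study	79.0	306	XV	54.5
mms4d	this_study	46.3	32	III	32.7
mms4d	this_study	46.3	32	VII	50.0
mms4d	this_study	46.3	32	VIII	31.8
mms4d	this_study	46.3	32	XV	83.4
mms4d	ref	45.4	272	III	25.2
mms4d	ref	45.4	272	VII	62.1
mms4d	ref	45.4	272	VIII	35.3
mlh3d mms4d	this_study	61.9	170	III	5.7
mlh3d mms4d	this_study	61.9	170	VII	9.6
mlh3d mms4d	this_study	61.9	170	VIII	2.8
mlh3d mms4d	this_study	61.9	170	XV	8.4
fold decrease	fold	NA	NA	III	6.1
fold decrease	fold	NA	NA	VII	7.2
fold decrease	fold	NA	NA	VIII	16.5
fold decrease	fold	NA	NA	XV	11.4
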