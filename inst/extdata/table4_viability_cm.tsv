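# Spore viability (%) and cumulative chromosome XV map distance (cM) from
# four-spore-viable tetrads (n_tetrads dissected). group marks the strain panel;
# the 'mlh3' group (10 strains) is the viability-vs-distance regression set.
strain	group	spore_viability_pct	cumulative_cM	n_tetrads	mmr
MLH3	mlh3	97.0	100.9	1068	+
mlh3d	mlh3	71.7	54.5	582	-
mlh3-E31A	mlh3	89.2	67.0	330	-
mlh3-N35A	mlh3	72.7	51.5	229	-
mlh3-A41F	mlh3	71.6	51.2	214	-
mlh3-G63R	mlh3	74.1	51.2	216	-
mlh3-K80E	mlh3	71.8	49.8	221	-
mlh3-K83A	mlh3	94.1	100.5	289	+
mlh3-R96A	mlh3	82.4	76.4	177	-
mlh3-G97A	mlh3	81.5	61.0	210	-
msh5d	msh5	36.0	37.0	540	NA
msh5d mlh3d	msh5	31.8	38.5	43	NA
msh5-D76A	msh5	87.8	53.9	77	NA
msh5-T423A	msh5	95.2	78.3	101	NA
msh5-D76A mlh3-R96A	msh5	57.8	45.0	81	NA
msh5-D76A mlh3-G97A	msh5	47.1	31.7	82	NA
msh5-T423A mlh3-R96A	msh5	89.6	60.9	160	NA
msh5-T423A mlh3-G97A	msh5	78.3	54.7	130	NA
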