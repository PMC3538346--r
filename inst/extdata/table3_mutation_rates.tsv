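# lys2::InsE-A14 reversion assay: median mutation rates (x1e-7) with 95% CIs
# and rates relative to wild type. Deletion alleles carry an ASCII 'd' suffix.
genotype	n	median_rate_e7	ci_low_e7	ci_high_e7	relative
MLH3	110	4.71	3.87	5.11	1.0
mlh3d	110	26.5	23.5	30.4	5.7
mlh3-E31A	15	30.5	16.7	51.6	6.5
mlh3-N35A	15	31.2	25.6	44.4	6.7
mlh3-A41F	15	27.9	17.1	34.3	6.0
mlh3-G63R	15	23.8	18.2	37.1	5.1
mlh3-K80E	15	16.0	15.1	27.7	3.4
mlh3-K83A	15	5.24	3.49	6.34	1.1
mlh3-R96A	15	14.8	6.42	40.6	3.2
mlh3-G97A	15	16.6	11.8	26.0	3.6
MLH3 + empty vector	11	4.42	1.02	6.05	1
MLH3 + pGAL10-MLH3	11	39100	15700	79900	8850
MLH3 + pGAL10-mlh3E31A	11	47800	28700	85900	10800
MLH3 + pGAL10-mlh3R96A	11	23500	5910	38400	5320
MLH3 + pGAL10-mlh3G97A	11	96000	45800	156000	21700
mlh1d + empty vector	11	218000	121000	283000	49300
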