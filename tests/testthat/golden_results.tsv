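snp_names	k	g	df	p_value	excluded_genotypes	untestable	significant	threshold	combo_id
SNP6,SNP7	2	99.2499408668932	7	1.54100697453987e-18	2-2	FALSE	TRUE	0.000114942528735632	6,7
SNP7,SNP27	2	61.4350052516553	5	6.13805295830778e-12	0-2;1-2;2-2	FALSE	TRUE	0.000114942528735632	7,27
SNP2,SNP7	2	63.8235121686667	7	2.59095845506217e-11	2-2	FALSE	TRUE	0.000114942528735632	2,7
SNP7,SNP26	2	52.5742428503126	7	4.49854054859686e-09	2-0	FALSE	TRUE	0.000114942528735632	7,26
SNP7,SNP28	2	54.4305932448267	8	5.69536401076831e-09		FALSE	TRUE	0.000114942528735632	7,28
SNP7,SNP25	2	51.360877132571	7	7.80171057432137e-09	2-2	FALSE	TRUE	0.000114942528735632	7,25
SNP4,SNP7	2	48.3657666753977	6	9.98555934969643e-09	2-0;2-2	FALSE	TRUE	0.000114942528735632	4,7
SNP7,SNP22	2	52.7255974387195	8	1.21868418590689e-08		FALSE	TRUE	0.000114942528735632	7,22
SNP7,SNP29	2	42.3035916863212	4	1.44311427662594e-08	0-2;1-2;2-1;2-2	FALSE	TRUE	0.000114942528735632	7,29
SNP7,SNP23	2	41.1889763619903	5	8.59309663432744e-08	0-2;1-2;2-2	FALSE	TRUE	0.000114942528735632	7,23
SNP7,SNP11	2	45.4328910352599	8	3.04610999482086e-07		FALSE	TRUE	0.000114942528735632	7,11
SNP7,SNP15	2	34.9620292596906	4	4.72952601875706e-07	0-2;1-2;2-1;2-2	FALSE	TRUE	0.000114942528735632	7,15
SNP3,SNP7	2	35.4479461269884	5	1.22459872196036e-06	2-0;2-2	FALSE	TRUE	0.000114942528735632	3,7
SNP23,SNP29	2	7.03250035745131	3	0.0708690584079553	0-2;1-2;2-0	FALSE	FALSE	0.000114942528735632	23,29
SNP8,SNP29	2	8.15046595828354	4	0.0862193586648803	0-2;1-2	FALSE	FALSE	0.000114942528735632	8,29
SNP3,SNP23	2	6.1511953285824	3	0.104481526717254	0-2;2-0;2-1	FALSE	FALSE	0.000114942528735632	3,23
SNP8,SNP23	2	5.94824615126051	3	0.114155491109782	0-2;1-2;2-0;2-1	FALSE	FALSE	0.000114942528735632	8,23
SNP13,SNP29	2	5.41691802133196	4	0.247129551133462	0-2;2-1	FALSE	FALSE	0.000114942528735632	13,29
SNP15,SNP29	2	3.21349352192924	3	0.359865340137732	0-2;1-2;2-0	FALSE	FALSE	0.000114942528735632	15,29
SNP3,SNP29	2	2.68135982005843	3	0.443404297557931	0-2;1-2;2-0;2-1	FALSE	FALSE	0.000114942528735632	3,29
SNP15,SNP23	2	1.84213654208863	3	0.605808758309622	0-2;1-2;2-0;2-1	FALSE	FALSE	0.000114942528735632	15,23
SNP3,SNP15	2	-2.19061639655116	3	1	0-2;1-2;2-0;2-1	FALSE	FALSE	0.000114942528735632	3,15
SNP3,SNP8	2	-0.63034602476413	3	1	0-2;1-2;2-0;2-1	FALSE	FALSE	0.000114942528735632	3,8
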