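study_id	paradigm	n_subjects	x	y	z	space
doe2015	execution	14	-38	-22	54	MNI
doe2015	execution	14	36	-20	52	MNI
doe2015	execution	14	-2	-8	50	MNI
rivera2018a	execution	21	-40	-24	56	MNI
rivera2018a	execution	21	-22	-4	-4	MNI
kim2012	imagery	12	-36	-6	52	MNI
kim2012	imagery	12	-44	30	28	Talairach
kim2012	imagery	12	28	-62	-24	MNI
sato2019a	imagery	18	-34	-4	54	MNI
sato2019a	imagery	18	-46	32	26	MNI
sato2019b	imagery	18	34	-58	-22	MNI
okafor2016	working_memory	25	-42	32	30	MNI
okafor2016	working_memory	25	-34	-2	56	MNI
okafor2016	working_memory	25	40	36	28	MNI
lund2013	working_memory	16	-44	28	32	Talairach
lund2013	working_memory	16	2	16	46	MNI
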