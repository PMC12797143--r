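variant	row	c1	c2	c3	c4
spm	1	0.9254	0.0024	-0.0118	-1.0207
spm	2	-0.0048	0.9316	-0.0871	-1.7667
spm	3	0.0152	0.0883	0.8924	4.0926
fsl	1	0.9464	0.0034	-0.0026	-1.0680
fsl	2	-0.0083	0.9479	-0.0580	-1.0239
fsl	3	0.0053	0.0617	0.9010	3.1883
pooled	1	0.9357	0.0029	-0.0072	-1.0423
pooled	2	-0.0065	0.9396	-0.0726	-1.3940
pooled	3	0.0103	0.0752	0.8967	3.6475
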