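paradigm	papers	experiments	participants	foci
execution	71	107	1687	1842
imagery	134	216	3349	3214
working_memory	492	492	11323	10086
all	697	815	16359	15142
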