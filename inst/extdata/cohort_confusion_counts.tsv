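train	test	tp	fn	fp	tn
BIOS90	BIOS10	95	231	35	2414
BIOS90	GTEx_full	882	2140	518	22249
GTEx90	BIOS_full	1242	2101	667	23739
GTEx90	GTEx10	77	220	17	2265
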