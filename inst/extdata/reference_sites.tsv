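enzyme	resno	resname	site
AtSHT	155	H	catalytic
AtSDT	169	H	catalytic
AtSHT	246	R	coa-adenosine
AtSHT	263	R	coa-adenosine
AtSHT	387	S	coa-adenosine
AtSHT	390	T	coa-adenosine
AtSHT	265	E	coa-diphosphate
AtSHT	262	T	coa-diphosphate
AtSHT	298	R	coa-diphosphate
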