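resno	resname	role
40	D	vdw
43	N	vdw
47	Y	water-mediated
292	G	vdw
294	S	h-bond
314	Y	vdw
316	D	h-bond
318	Y	vdw
354	E	vdw
358	T	vdw
377	C	vdw
379	T	water-mediated
381	W	water-mediated
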