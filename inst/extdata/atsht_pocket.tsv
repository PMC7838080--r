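resno	resname	role
33	T	h-bond
37	I	vdw
290	G	vdw
292	C	vdw
312	T	vdw
314	D	h-bond
386	V	vdw
411	H	water-mediated
416	D	water-mediated
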