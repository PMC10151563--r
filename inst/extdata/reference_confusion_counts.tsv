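assay	a	b	c	d
promega	45	17	3	3
seq24	54	8	1	9
seq54	58	4	3	7
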