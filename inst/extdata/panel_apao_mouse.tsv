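ref_id	pos	expected_aa
MmAPAO	62	W
MmAPAO	64	H
MmAPAO	315	K
MmAPAO	430	Y
MmAPAO	473	S
MmAPAO	474	T
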