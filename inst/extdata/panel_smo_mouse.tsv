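ref_id	pos	expected_aa
MmSMO	80	W
MmSMO	82	H
MmSMO	200	Q
MmSMO	216	E
MmSMO	218	S
MmSMO	224	E
MmSMO	367	K
MmSMO	427	W
MmSMO	482	Y
MmSMO	527	S
MmSMO	528	T
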