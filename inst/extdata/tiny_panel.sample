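sample_id	population	region
r1	P1	X
r2	P1	X
r3	P2	X
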