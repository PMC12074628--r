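start	end	region
1	10	cytoplasmic interface
11	30	transmembrane helix 1
31	57	ER-luminal region
58	75	cap domain
76	82	cap-domain anchor
83	97	membrane-exposed segment
98	106	cytoplasmic interface
107	125	transmembrane helix
126	161	transmembrane helix / binding pocket wall
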