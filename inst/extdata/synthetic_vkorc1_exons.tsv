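species_id	exon_index	start	end
Rattus_norvegicus	1	1	160
Rattus_norvegicus	2	161	326
Rattus_norvegicus	3	327	483
Rattus_rattus	1	1	160
Rattus_rattus	2	161	326
Rattus_rattus	3	327	483
Mus_musculus	1	1	157
Mus_musculus	2	158	330
Mus_musculus	3	331	483
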