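species_scope	codon_index	ref_codon	alt_codon	label	status	evidence
Rattus_norvegicus,Rattus_rattus	7	AGC	GGC	S7G	novel	newly identified in this survey
Rattus_norvegicus,Rattus_rattus	12	CGG	CGA	A12A	known_other	silent background; printed without status letter
Rattus_norvegicus,Rattus_rattus	28	CAC	CAG	H28Q	novel	newly identified in this survey; H28Q confers warfarin resistance in human
Rattus_norvegicus,Rattus_rattus	35	CGC	CGT	R35R	known_other	silent background; printed without status letter
Rattus_norvegicus,Rattus_rattus	36	AAT	CAT	N36H	novel	newly identified in this survey
Rattus_norvegicus,Rattus_rattus	41	GCG	GCA	A41A	known_other	silent background; printed without status letter
Rattus_norvegicus,Rattus_rattus	42	CTC	CCC	L42P	novel	newly identified in this survey
Rattus_norvegicus,Rattus_rattus	59	TGG	AGG	W59R	resistance_associated	confers resistance in vivo in the brown rat
Rattus_norvegicus,Rattus_rattus	61	CGG	TGG	R61W	resistance_associated	known anticoagulant-resistance mutation
Rattus_norvegicus,Rattus_rattus	82	ATA	ATT	I82I	known_other	silent background; printed without status letter
Rattus_rattus	90	ATA	TTA	I90L	species_fixed	wild-type codon 90 is Ile in R. norvegicus but Leu in R. rattus
Rattus_norvegicus,Rattus_rattus	94	TTA	CTA	L94L	known_other	silent background; printed without status letter
Rattus_norvegicus,Rattus_rattus	96	TGC	GGC	C96G	novel	newly identified in this survey
Rattus_norvegicus,Rattus_rattus	107	ATC	ATA	I107I	known_other	silent background; printed without status letter
Rattus_norvegicus,Rattus_rattus	123	ATC	TTC	I123F	novel	newly identified in this survey
Rattus_norvegicus,Rattus_rattus	123	ATC	AGC	I123S	known_other	already described in the literature; resistance association unknown
Rattus_norvegicus,Rattus_rattus	137	ACC	ACT	T137T	known_other	silent background; printed without status letter
Rattus_norvegicus,Rattus_rattus	139	TAT	TTT	Y139F	resistance_associated	widespread warfarin-resistance mutation
Rattus_norvegicus,Rattus_rattus	143	GCG	GCA	A143A	known_other	silent background; printed without status letter
Mus_musculus	78	CAA	CAC	Q78H	novel	newly identified in this survey
Mus_musculus	85	TGC	CGC	C85R	novel	newly identified in this survey
Mus_musculus	87	TTC	TTA	F87L	novel	newly identified in this survey
Mus_musculus	128	TTA	TCA	L128S	resistance_associated	known anticoagulant-resistance mutation
Mus_musculus	139	TAT	TGT	Y139C	resistance_associated	known anticoagulant-resistance mutation
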