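# published downstream CpG-island methylation (%) of tandem-oriented
# genes, three lung-cancer lines vs two normal lung samples
region_id	gene	A549	H322	A427	NLu1	NLu2
chr2:201450526-201451027	AOX1	82	94	94	6	5
chr3:50377803-50378540	RASSF1A	93	91	91	7	8
chr11:2907308-2907675	CDKN1C	51	38	51	17	15
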