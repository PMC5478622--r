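# published per-cell-line CpG-island promoter methylation (%), three
# lung-cancer lines vs normal bronchial epithelial cells
region_id	gene	A427	A549	H322	NHBEC
chr11:72975469-72975797	P2RY6	99	97	99	2
chr3:50377803-50378540	RASSF1A	91	93	91	13
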