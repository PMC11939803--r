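#BioGRID Interaction ID	Entrez Gene Interactor A	Entrez Gene Interactor B	Official Symbol Interactor A	Official Symbol Interactor B	Experimental System
1	7157	4193	TP53	MDM2	Two-hybrid
2	7157	7157	TP53	TP53	Two-hybrid
3	4193	1956	MDM2	EGFR	Affinity Capture-MS
4	1956	3845	EGFR	KRAS	Affinity Capture-MS
5	3845	7157	KRAS	TP53	Two-hybrid
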