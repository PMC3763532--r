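cluster_id	source	lineage	original_mirna	notes
999/4969	NewHairpin	Melanogaster	dme-mir-999	Original miRNA: mir-999
982/303/983-1/983-2/984	NewHairpin	Melanogaster	NA	Multiple emergence within a conserved gene
969/210	NewHairpin	Drosophila	dme-mir-210	Original microRNA: mir-210
124/287	NewHairpin	Drosophila	dme-mir-124	Original microRNA: mir-124
972/973/974/2499/4966/975/976/977/978/979	NewHairpin	Drosophila	NA	
959/960/961/962/963/964	NewHairpin	Drosophila	NA	
1002/968	NewHairpin	Drosophila	NA	
281-2/281-1	Duplication	Drosophila	NA	
310/311/312/313/2498/991/992	Duplication	Drosophila	NA	Probably two clusters: 310/311/312/313 and 2498/991/992
6-3/6-2/6-1/5/4/286/3/309	NewHairpin	Insects	NA	Cluster may be older (see main text)
998/11	NewHairpin	Insects	NA	
994/318	NewHairpin	Insects	NA	
279/996	Duplication	Insects	NA	
9c/306/79/9b	Unknown	Insects	NA	
283/304/12	NewHairpin	Protostomes	NA	
275/305	NewHairpin	Protostomes	NA	
317/277/34	NewHairpin	Protostomes	dme-mir-34	Original microRNA: mir-34
13b-1/13a/2c	Duplication	Protostomes	NA	The original mir-2 cluster probably emerged by de novo acquisition of mir-2 nearby mir-71 (see main text)
2a-2/2a-1/2b-2	Duplication	Protostomes	NA	The original mir-2 cluster probably emerged by de novo acquisition of mir-2 nearby mir-71 (see main text)
92a/92b	Duplication	Metazoans	NA	Duplications in insects and chordates may be independent
100/let-7/125	Unknown	Metazoans	NA	mir-100 and mir-125 are paralogs
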