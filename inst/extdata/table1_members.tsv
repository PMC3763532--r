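cluster_id	position	mirna_id	annotation_family	phylo_family	age_lineage	chrom	start	end	strand
999/4969	1	dme-mir-999	mir-999	mir-999	Insects	2L	400137	400234	+
999/4969	2	dme-mir-4969	mir-4969	mir-4969	Melanogaster	2L	400440	400544	+
982/303/983-1/983-2/984	1	dme-mir-982	mir-982	mir-982	Melanogaster	2R	400274	400351	+
982/303/983-1/983-2/984	2	dme-mir-303	mir-303	mir-303	Drosophila	2R	400586	400670	+
982/303/983-1/983-2/984	3	dme-mir-983-1	mir-983	mir-983	Melanogaster	2R	400958	401049	+
982/303/983-1/983-2/984	4	dme-mir-983-2	mir-983	mir-983	Melanogaster	2R	401390	401488	+
982/303/983-1/983-2/984	5	dme-mir-984	mir-984	mir-984	Melanogaster	2R	401882	401987	+
969/210	1	dme-mir-969	mir-969	mir-969	Drosophila	3L	400411	400501	-
969/210	2	dme-mir-210	mir-210	mir-210	Metazoans	3L	400765	400862	-
124/287	1	dme-mir-124	mir-124	mir-124	Metazoans	3R	400548	400651	+
124/287	2	dme-mir-287	mir-287	mir-287	Drosophila	3R	400944	401021	+
972/973/974/2499/4966/975/976/977/978/979	1	dme-mir-972	mir-972	mir-972	Insects	X	400685	400768	-
972/973/974/2499/4966/975/976/977/978/979	2	dme-mir-973	mir-973	mir-973	Drosophila	X	401090	401180	-
972/973/974/2499/4966/975/976/977/978/979	3	dme-mir-974	mir-974	mir-974	Drosophila	X	401555	401652	-
972/973/974/2499/4966/975/976/977/978/979	4	dme-mir-2499	mir-2499	mir-2499	Drosophila	X	402080	402184	-
972/973/974/2499/4966/975/976/977/978/979	5	dme-mir-4966	mir-4966	mir-4966	Drosophila	X	402665	402743	-
972/973/974/2499/4966/975/976/977/978/979	6	dme-mir-975	mir-975	mir-975	Drosophila	X	403277	403362	-
972/973/974/2499/4966/975/976/977/978/979	7	dme-mir-976	mir-976	mir-976	Drosophila	X	403469	403561	-
972/973/974/2499/4966/975/976/977/978/979	8	dme-mir-977	mir-977	mir-977	Drosophila	X	403721	403820	-
972/973/974/2499/4966/975/976/977/978/979	9	dme-mir-978	mir-978	mir-978	Drosophila	X	404033	404139	-
972/973/974/2499/4966/975/976/977/978/979	10	dme-mir-979	mir-979	mir-979	Drosophila	X	404405	404485	-
959/960/961/962/963/964	1	dme-mir-959	mir-959	mir-959	Insects	2L	750822	750918	+
959/960/961/962/963/964	2	dme-mir-960	mir-960	mir-960	Drosophila	2L	751269	751372	+
959/960/961/962/963/964	3	dme-mir-961	mir-961	mir-961	Drosophila	2L	751776	751853	+
959/960/961/962/963/964	4	dme-mir-962	mir-962	mir-962	Drosophila	2L	752310	752394	+
959/960/961/962/963/964	5	dme-mir-963	mir-963	mir-963	Drosophila	2L	752904	752995	+
959/960/961/962/963/964	6	dme-mir-964	mir-964	mir-964	Drosophila	2L	753078	753176	+
1002/968	1	dme-mir-1002	mir-1002	mir-1002	Drosophila	2R	750959	751068	+
1002/968	2	dme-mir-968	mir-968	mir-968	Insects	2R	751448	751531	+
281-2/281-1	1	dme-mir-281-2	mir-281	mir-281	Drosophila	3L	751096	751185	-
281-2/281-1	2	dme-mir-281-1	mir-281	mir-281	Drosophila	3L	751594	751690	-
310/311/312/313/2498/991/992	1	dme-mir-310	mir-310	mir-310	Drosophila	3R	751233	751335	+
310/311/312/313/2498/991/992	2	dme-mir-311	mir-310	mir-310	Drosophila	3R	751773	751882	+
310/311/312/313/2498/991/992	3	dme-mir-312	mir-310	mir-310	Drosophila	3R	752373	752456	+
310/311/312/313/2498/991/992	4	dme-mir-313	mir-310	mir-310	Drosophila	3R	753000	753090	+
310/311/312/313/2498/991/992	5	dme-mir-2498	mir-2498	mir-2498	Melanogaster	3R	753207	753304	+
310/311/312/313/2498/991/992	6	dme-mir-991	mir-991	mir-991	Melanogaster	3R	753474	753578	+
310/311/312/313/2498/991/992	7	dme-mir-992	mir-992	mir-992	Melanogaster	3R	753801	753879	+
6-3/6-2/6-1/5/4/286/3/309	1	dme-mir-6-3	mir-6	mir-6	Insects	X	751370	751452	+
6-3/6-2/6-1/5/4/286/3/309	2	dme-mir-6-2	mir-6	mir-6	Insects	X	751919	752008	+
6-3/6-2/6-1/5/4/286/3/309	3	dme-mir-6-1	mir-6	mir-6	Insects	X	752528	752624	+
6-3/6-2/6-1/5/4/286/3/309	4	dme-mir-5	mir-5	mir-5	Insects	X	752717	752820	+
6-3/6-2/6-1/5/4/286/3/309	5	dme-mir-4	mir-4	mir-4	Insects	X	752966	753043	+
6-3/6-2/6-1/5/4/286/3/309	6	dme-mir-286	mir-286	mir-286	Insects	X	753242	753326	+
6-3/6-2/6-1/5/4/286/3/309	7	dme-mir-3	mir-3	mir-3	Insects	X	753578	753669	+
6-3/6-2/6-1/5/4/286/3/309	8	dme-mir-309	mir-309	mir-309	Protostomes	X	753974	754072	+
998/11	1	dme-mir-998	mir-998	mir-998	Insects	2L	1101507	1101602	-
998/11	2	dme-mir-11	mir-11	mir-11	Protostomes	2L	1102098	1102200	-
994/318	1	dme-mir-994	mir-994	mir-994	Insects	2R	1101644	1101752	+
994/318	2	dme-mir-318	mir-318	mir-318	Protostomes	2R	1102277	1102359	+
279/996	1	dme-mir-279	mir-279	mir-279	Insects	3L	1101781	1101869	+
279/996	2	dme-mir-996	mir-996	mir-279	Insects	3L	1101943	1102038	+
9c/306/79/9b	1	dme-mir-9c	mir-9	mir-9c	Insects	3R	1101918	1102019	+
9c/306/79/9b	2	dme-mir-306	mir-306	mir-306	Insects	3R	1102122	1102230	+
9c/306/79/9b	3	dme-mir-79	mir-9	mir-79	Drosophila	3R	1102386	1102468	+
9c/306/79/9b	4	dme-mir-9b	mir-9	mir-9b	Drosophila	3R	1102677	1102766	+
283/304/12	1	dme-mir-283	mir-283	mir-283	Protostomes	X	1102055	1102136	-
283/304/12	2	dme-mir-304	mir-304	mir-304	Protostomes	X	1102268	1102356	-
283/304/12	3	dme-mir-12	mir-12	mir-12	Metazoans	X	1102541	1102636	-
275/305	1	dme-mir-275	mir-275	mir-275	Protostomes	2L	1452192	1452286	+
275/305	2	dme-mir-305	mir-305	mir-305	Metazoans	2L	1452447	1452548	+
317/277/34	1	dme-mir-317	mir-317	mir-317	Protostomes	2R	1452329	1452436	+
317/277/34	2	dme-mir-277	mir-277	mir-277	Protostomes	2R	1452626	1452707	+
317/277/34	3	dme-mir-34	mir-34	mir-34	Metazoans	2R	1452950	1453038	+
13b-1/13a/2c	1	dme-mir-13b-1	mir-2	mir-2	Protostomes	3L	1452466	1452553	+
13b-1/13a/2c	2	dme-mir-13a	mir-2	mir-2	Protostomes	3L	1452772	1452866	+
13b-1/13a/2c	3	dme-mir-2c	mir-2	mir-2	Protostomes	3L	1453138	1453239	+
2a-2/2a-1/2b-2	1	dme-mir-2a-2	mir-2	mir-2	Protostomes	3R	1452603	1452703	-
2a-2/2a-1/2b-2	2	dme-mir-2a-1	mir-2	mir-2	Protostomes	3R	1452951	1453058	-
2a-2/2a-1/2b-2	3	dme-mir-2b-2	mir-2	mir-2	Protostomes	3R	1453359	1453440	-
92a/92b	1	dme-mir-92a	mir-92	mir-92	Metazoans	X	1452740	1452820	+
92a/92b	2	dme-mir-92b	mir-92	mir-92	Metazoans	X	1453097	1453184	+
100/let-7/125	1	dme-mir-100	mir-100	mir-100	Metazoans	2L	1802877	1802970	+
100/let-7/125	2	dme-let-7	let-7	let-7	Metazoans	2L	1803276	1803376	+
100/let-7/125	3	dme-mir-125	mir-125	mir-125	Metazoans	2L	1803735	1803842	+
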