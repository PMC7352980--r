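K	class	ESR	VDR	COX2	CTSD	F_printed
1	ESR	0.4623	0.2172	0.0082	0.3123	0.9272
1	VDR	0.1116	0.5101	0.0054	0.3729	1.0205
1	COX2	0.0882	0.3216	0.2046	0.3856	0.5071
1	CTSD	0.0051	0.0489	0.0057	0.9404	3.9718
3	ESR	0.3289	0.2616	0.0725	0.3370	0.7001
3	VDR	0.1653	0.5199	0.0517	0.2631	1.0406
3	COX2	0.1024	0.4922	0.1534	0.2520	0.4257
3	CTSD	0.1348	0.0741	0.0128	0.7783	1.8738
7	ESR	0.3669	0.2553	0.0713	0.3065	0.7613
7	VDR	0.2164	0.5005	0.0476	0.2356	1.0009
7	COX2	0.1387	0.4891	0.1477	0.2245	0.4164
7	CTSD	0.1437	0.0705	0.0084	0.7775	1.8691
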