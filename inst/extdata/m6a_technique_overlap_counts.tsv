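technique	m6A-seq	PA-m6A-seq	miCLIP	m6A-CLIP-seq	m6A-REF-seq	MAZTER-seq	DART-seq	m6ACE-seq	m6A-Label-seq
m6A-seq	2980	325	1743	1474	105	2	14	69	98
PA-m6A-seq	NA	6828	2181	1522	202	88	160	123	134
miCLIP	NA	NA	22499	9005	948	265	657	466	625
m6A-CLIP-seq	NA	NA	NA	15649	742	142	456	411	581
m6A-REF-seq	NA	NA	NA	NA	3736	47	103	16	67
MAZTER-seq	NA	NA	NA	NA	NA	5265	141	0	8
DART-seq	NA	NA	NA	NA	NA	NA	3714	10	18
m6ACE-seq	NA	NA	NA	NA	NA	NA	NA	640	37
m6A-Label-seq	NA	NA	NA	NA	NA	NA	NA	NA	1244
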