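platform	impact	consequence	common	exclusive
WES	high	frameshift	1440	109
WES	high	splice_acceptor	69	14
WES	high	splice_donor	107	14
WES	high	start_lost	11	0
WES	high	stop_gained	16	5
WES	high	stop_lost	12	1
WES	high	All	1602	137
WES	moderate	inframe_deletion	709	74
WES	moderate	inframe_insertion	557	46
WES	moderate	protein_altering	13	3
WES	moderate	All	1267	122
WES	low	3_prime_UTR	173	16
WES	low	5_prime_UTR	194	7
WES	low	splice_region	641	35
WES	low	start_retained	7	0
WES	low	stop_retained	10	0
WES	low	All	299	18
WES	All	All	4333	351
WGS	high	frameshift	1451	260
WGS	high	splice_acceptor	71	31
WGS	high	splice_donor	107	25
WGS	high	start_lost	11	2
WGS	high	stop_gained	17	13
WGS	high	stop_lost	12	2
WGS	high	All	1615	316
WGS	moderate	inframe_deletion	710	69
WGS	moderate	inframe_insertion	557	62
WGS	moderate	protein_altering	13	11
WGS	moderate	All	1268	139
WGS	low	3_prime_UTR	176	40
WGS	low	5_prime_UTR	195	18
WGS	low	splice_region	644	49
WGS	low	start_retained	7	0
WGS	low	stop_retained	10	2
WGS	low	All	302	23
WGS	All	All	4364	609
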