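platform	impact	consequence	common	exclusive
WES	high	splice_acceptor	97	3
WES	high	splice_donor	137	3
WES	high	start_lost	63	2
WES	high	stop_gained	237	5
WES	high	stop_lost	35	0
WES	high	All	569	13
WES	moderate	missense	43518	309
WES	moderate	All	43516	309
WES	low	3_prime_UTR	2022	43
WES	low	5_prime_UTR	2458	13
WES	low	splice_region	3938	21
WES	low	stop_retained	60	0
WES	low	synonymous	87341	321
WES	low	All	88584	336
WES	All	All	144012	834
WGS	high	splice_acceptor	98	11
WGS	high	splice_donor	139	19
WGS	high	start_lost	63	0
WGS	high	stop_gained	232	18
WGS	high	stop_lost	36	1
WGS	high	All	568	49
WGS	moderate	missense	43419	821
WGS	moderate	All	43417	821
WGS	low	3_prime_UTR	2031	114
WGS	low	5_prime_UTR	2459	35
WGS	low	splice_region	3923	50
WGS	low	stop_retained	58	2
WGS	low	synonymous	87182	956
WGS	low	All	88417	975
WGS	All	All	143745	2194
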