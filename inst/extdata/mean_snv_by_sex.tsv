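grouping	platform	chrom_class	mean_male	mean_female	printed_difference	printed_pct
top50_outliers	WGS	autosome	1595.00	1445.67	149.33	9.36
top50_outliers	WES	autosome	946.25	872.83	73.42	7.76
top50_outliers	WGS	X	1363.75	22.83	1340.92	98.33
top50_outliers	WES	X	829.75	23.00	806.75	97.73
all_genes	WGS	autosome	53724.75	57605.50	3880.75	7.22
all_genes	WES	autosome	53189.50	57217.67	4028.17	7.57
all_genes	WGS	X	1968.50	766.00	1202.50	61.09
all_genes	WES	X	1412.00	776.33	635.67	45.02
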