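case_id	germline_hr_gene	germline_variant	somatic_hr_inactivation	somatic_detail	hrdetect	low_cellularity	germline_mmr_gene	mmr_ihc_mlh1	mmr_ihc_msh2	mmr_ihc_msh6	mmr_ihc_pms2	msisensor
348.001	BRCA1	c.2681_2682delAA	FALSE		NA	FALSE		retained	retained	retained	retained	NA
1048.001	BRCA1	c.1018C>T	TRUE	BRCA1 LOH	0.999	FALSE		not_assessed	not_assessed	not_assessed	not_assessed	1.76
PCSI_0476	BRCA1	c.5319dupC	TRUE	BRCA1 deletion	0.999	FALSE		not_assessed	not_assessed	not_assessed	not_assessed	2.05
70.001	BRCA2	c.3398del5	TRUE	BRCA2 c.1794_1798del	0.999	FALSE		retained	retained	retained	retained	2.17
99.001	BRCA2	c.4691dupC	FALSE		NA	FALSE		retained	retained	retained	retained	NA
392.001	BRCA2	c.8677C>T	TRUE	BRCA2 c.2050C>T	0.999	FALSE		retained	retained	retained	retained	1.62
543.001	BRCA2	c.3545delTT	FALSE		NA	FALSE		retained	retained	retained	retained	NA
908.001	BRCA2	c.8297delC	TRUE	BRCA2 LOH	0.999	FALSE		retained	retained	retained	retained	0.17
1024.001	BRCA2	c.1805_1806insA	TRUE	BRCA2 LOH	0.999	FALSE		not_assessed	not_assessed	not_assessed	not_assessed	2.2
1183.001	BRCA2	c.4284dup	FALSE		NA	FALSE		retained	retained	retained	retained	NA
1195.001	BRCA2	c.3170_3174del	FALSE		NA	FALSE		retained	retained	retained	retained	NA
1227.001	BRCA2	c.8537_8538del	FALSE		NA	FALSE		retained	retained	retained	retained	NA
1235.001	BRCA2	c.3170_3174del	FALSE		NA	FALSE		not_assessed	not_assessed	not_assessed	not_assessed	NA
1337.001	BRCA2	c.6275_6276del	FALSE		NA	FALSE		retained	retained	retained	retained	NA
PCSI_0017	BRCA2	c.5946delT	TRUE	BRCA2 LOH	0.999	FALSE		not_assessed	not_assessed	not_assessed	not_assessed	2.44
PCSI_0048	BRCA2	c.5946delT	TRUE	BRCA2 LOH	0.999	FALSE		retained	retained	retained	retained	0.96
PCSI_0075		-	TRUE	BRCA2 c.5718_5719del + c.6579A>G	0.999	FALSE		retained	retained	retained	retained	1.46
PCSI_0142	BRCA2	c.9435_9436delGT	TRUE	BRCA2 LOH	0.999	FALSE		retained	retained	retained	retained	1.74
PCSI_0176	BRCA2	c.3167_3170delAAAA	TRUE	BRCA2 LOH	0.999	FALSE		not_assessed	not_assessed	not_assessed	not_assessed	1.14
PCSI_0218	BRCA2	c.3167_3170delAAAA	TRUE	BRCA2 c.8910G>A	0.999	FALSE		retained	retained	retained	retained	0.73
PCSI_0472		-	TRUE	BRCA2 c.5718_5719del + c.316+1G>T	0.999	FALSE		not_assessed	not_assessed	not_assessed	not_assessed	2.32
PCSI_0477	BRCA2	c.9097dupA	TRUE	BRCA2 LOH	0.999	FALSE		not_assessed	not_assessed	not_assessed	not_assessed	1.69
PCSI_0492	BRCA2	c.4003G>T	TRUE	BRCA2 LOH	0.999	FALSE		not_assessed	not_assessed	not_assessed	not_assessed	2.80
303.001	PALB2	c.2323C>T	TRUE	PALB2 c.2174C>G	0.742	TRUE		retained	retained	retained	retained	1.36
1099.001	PALB2	exon 11 deletion	FALSE		NA	FALSE		retained	retained	retained	retained	NA
750.001		-	FALSE		NA	FALSE	MSH2	retained	lost	lost	retained	NA
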