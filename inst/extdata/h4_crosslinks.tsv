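id	reliability	h4_probe	construct	mass_obs	error_ppm	alpha_seq	alpha_site	beta_seq	beta_site	inferred_ox
XL11	high	nucleosomal	ISWI_WT	2034.8571	-0.2	XGR	1	QIQEFNMDNSAK	495	FALSE
XL12	high	nucleosomal	SNF2H	2251.9753	-0.4	GXGK	10	VLDILEDYCMWR	520	FALSE
XL13a	high	peptide	ISWI_26-648	1648.7601	-0.4	BGR	1	LDGQTPHEDR	482	FALSE
XL13b	high	peptide	ISWI_26-648	1918.9052	-0.9	BGR	1	LDGQTPHEDRNR	482	FALSE
XL13c	high	peptide	ISWI_26-648	3340.5374	-2.8	BGR	1	LDGQTPHEDRNRQIQEFNM[ox]DNSAK	482	TRUE
XL14	medium	nucleosomal	SNF2H	2222.9624	-1.5	XGR	1	VLDILEDYCMWR	519-522	FALSE
XL15	medium	peptide	ISWI_26-648	1257.6261	2.3	BGR	1	M[ox]VIQGGR	578	TRUE
XL16	medium	peptide	ISWI_26-648	1424.7832	-3.9	BGR	1	IVERAEVK	568	FALSE
XL17	medium	peptide	ISWI_26-648	1453.7998	-4.6	GBGK	10	IVERAEVK	568	FALSE
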