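id	mass_obs	error_ppm	alpha_seq	alpha_site	beta_seq	beta_site	inferred_ox
XL1	3220.4946	-1.9	LDGQTPBEDRNR	483	QTEIFTHFM[ox]TNSAK	59-60	FALSE
XL2	3204.5056	-3.7	LDGQTPBEDRNR	483	QTEIFTHFMTNSAK	60-61	FALSE
XL3	2950.3474	-1.0	LDGQTPBEDR	483	QTEIFTHFM[ox]TNSAK	55-59	FALSE
XL4	2934.3571	-2.6	LDGQTPBEDR	483	QTEIFTHFMTNSAK	59-61	FALSE
XL5	2207.0968	0.2	LDGQTPBEDRNR	483	SPTKPK	69-72	FALSE
XL6	1936.9645	-6.1	LDGQTPBEDR	483	SPTKPK	71-72	FALSE
XL7	1736.8594	-6.1	LDGQTPBEDR	483	GRPK	75	FALSE
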