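area	total_volume	full_mi	full_mi_wm	full_mi_ex	full_diff	full_pct_wm	full_pct_ex	full_diff_pct	matched_mi	matched_mi_wm	matched_mi_ex	matched_diff
AIPS_IP1	2805	649	640	37	603	98.6	5.7	92.9	482	428	34	394
Area 7	6194	1394	1269	0	1269	NA	NA	NA	829	440	0	440
Area 32	4009	327	313	70	243	NA	NA	NA	248	225	69	156
Area 45	3566	89	85	0	85	NA	NA	NA	20	11	0	11
DLPFC	8069	141	130	0	130	NA	NA	NA	34	17	0	17
Area 40	3975	1789	1305	279	1026	NA	NA	NA	1376	757	261	469
PMd	6599	2794	1845	240	1605	NA	NA	NA	2189	853	220	633
Area 44	2320	506	463	195	268	NA	NA	NA	331	236	164	72
IPL_PFcm	2555	753	16	122	-106	NA	NA	NA	488	0	99	-99
Cereb_VI	9020	734	492	305	187	NA	NA	NA	493	133	210	-77
S1	4288	645	235	437	-202	NA	NA	NA	296	28	216	-188
Area 2	1824	763	327	419	-92	NA	NA	NA	487	98	308	-210
IPL_PFt	3497	1580	735	553	182	NA	NA	NA	1068	345	390	-45
IPL_PF	5069	963	205	67	138	NA	NA	NA	569	60	49	11
Area 48	19932	2177	789	725	64	NA	NA	NA	1343	254	511	-257
PMv	5838	2038	1281	1024	257	NA	NA	NA	1506	544	834	-290
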