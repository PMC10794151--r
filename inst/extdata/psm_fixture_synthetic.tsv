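protein_id	gene	mw_kda	secreted	fraction	psm_vehicle	psm_pf	psm_protx
P0DMV8	HSPA1A	70.1	TRUE	30-100	0	9	7
P21741	MDK	15.6	TRUE	10-30	0	6	5
SYN0001	CAND1	45.2	TRUE	30-100	2	7	7
SYN0002	CAND2	82.4	TRUE	30-100	0	4	3
SYN0003	CAND3	12.8	TRUE	10-30	3	10	8
SYN0004	CAND4	24.5	TRUE	10-30	1	5	3
SYN0101	DECMW	8.9	TRUE	10-30	0	8	6
SYN0102	DECPF	55	TRUE	30-100	2	9	2
SYN0103	DECFOLD	28	TRUE	10-30	3	6	6
SYN0104	DECSEC	40	FALSE	30-100	1	10	10
SYN0201	BG01	25.6	TRUE	10-30	28	28	30
SYN0202	BG02	31.3	TRUE	30-100	20	22	19
SYN0203	BG03	14.7	TRUE	10-30	23	26	24
SYN0204	BG04	56.8	TRUE	30-100	18	19	17
SYN0205	BG05	28.5	TRUE	10-30	22	23	26
SYN0206	BG06	91.4	TRUE	30-100	29	30	33
SYN0207	BG07	22.1	TRUE	10-30	22	22	22
SYN0208	BG08	58.1	TRUE	30-100	31	33	30
SYN0209	BG09	24.5	TRUE	10-30	22	24	22
SYN0210	BG10	48.8	TRUE	30-100	28	29	29
SYN0211	BG11	28.7	TRUE	10-30	32	34	33
SYN0212	BG12	88.8	TRUE	30-100	17	17	17
SYN0213	BG13	25.9	TRUE	10-30	28	30	28
SYN0214	BG14	33.9	TRUE	30-100	27	27	27
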