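fast_id	slow_id	x_fast	x_slow	annotation
NM_182537	NM_182589	52	8	Serotonin receptor
NM_001083538	NM_001101	29	1	Actin beta
NM_002030	NM_001005738	51	15	Formyl peptide receptor
NM_001009562	NM_019844	77	34	Organic anion transporter
NM_001001659	NM_012365	32	12	Olfactory receptor
NM_000896	NM_001082	36	15	Cytochrome P450
NM_152631	NM_001013736	64	36	Unknown
NM_001004692	NM_001004695	13	2	Olfactory receptor
NM_145660	NM_145640	46	24	Apolipoprotein
NM_001006938	NM_001006933	10	1	Transcription elongation factor
NM_032098	NM_032099	48	27	Protocadherin gamma
NM_001004737	NM_001004736	11	2	Olfactory receptor
NM_001004743	NM_001005282	37	20	Olfactory receptor
NM_005557	NM_000526	40	8	Keratin 16
NM_020040	NM_177987	24	3	Tubulin beta polypeptide
NM_002699	NM_006236	15	0	POU class 3 homeobox
NM_017534	NM_005963	64	27	Myosin heavy chain
NM_001004482	NM_001004481	19	2	Olfactory receptor
NM_001004454	NM_001005236	50	20	Olfactory receptor
NM_001013435	NM_001015038	12	0	P antigen family
NM_000150	NM_002034	26	6	Fucosyltransferase
NM_001005479	NM_001005514	27	7	Olfactory receptor
NM_001005519	NM_054105	31	11	Olfactory receptor
NM_001005471	NM_030904	34	15	Olfactory receptor
NM_012373	NM_002551	17	5	Olfactory receptor
NM_032089	NM_014004	74	49	Protocadherin gamma
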