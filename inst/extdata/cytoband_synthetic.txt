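chr1	0	28000000	p36	gneg
chr1	28000000	34000000	p35	gpos
chr1	34000000	46000000	p34	gneg
chr1	46000000	50000000	p33	gpos
chr1	50000000	61000000	p32	gneg
chr1	61000000	69000000	p31.3	gpos
chr1	69000000	72000000	p31.2	gneg
chr1	72000000	84000000	p31.1	gpos
chr1	84000000	88000000	p22.3	gneg
chr1	88000000	91000000	p22.2	gpos
chr1	91000000	94000000	p22.1	gneg
chr1	94000000	107000000	p21	gpos
chr1	107000000	120000000	p13	gneg
chr1	120000000	122000000	p12	gpos
chr1	122000000	125000000	p11	acen
chr1	125000000	128000000	q11	acen
chr1	128000000	142000000	q12	gvar
chr1	142000000	156000000	q21	gneg
chr1	156000000	181000000	q23	gpos
chr1	181000000	197000000	q31	gneg
chr1	197000000	214000000	q32	gpos
chr1	214000000	224000000	q41	gneg
chr1	224000000	236000000	q42	gpos
chr1	236000000	244000000	q43	gneg
chr1	244000000	249250621	q44	gpos
chr4	0	4500000	p16.3	gneg
chr4	4500000	6000000	p16.2	gpos
chr4	6000000	11300000	p16.1	gneg
chr4	11300000	15200000	p15.33	gpos
chr4	15200000	17800000	p15.32	gneg
chr4	17800000	21300000	p15.31	gpos
chr4	21300000	27700000	p15.2	gneg
chr4	27700000	35800000	p15.1	gpos
chr4	35800000	41200000	p14	gneg
chr4	41200000	44600000	p13	gpos
chr4	44600000	48200000	p12	gneg
chr4	48200000	50400000	p11	acen
chr4	50400000	52700000	q11	acen
chr4	52700000	59500000	q12	gneg
chr4	59500000	75000000	q13	gpos
chr4	75000000	88000000	q21	gneg
chr4	88000000	98000000	q22	gpos
chr4	98000000	101000000	q23	gneg
chr4	101000000	107000000	q24	gpos
chr4	107000000	114000000	q25	gneg
chr4	114000000	124000000	q26	gpos
chr4	124000000	128000000	q27	gneg
chr4	128000000	139000000	q28	gpos
chr4	139000000	155000000	q31	gneg
chr4	155000000	170000000	q32	gpos
chr4	170000000	176000000	q33	gneg
chr4	176000000	183000000	q34	gpos
chr4	183000000	191154276	q35	gneg
chr6	0	7000000	p25	gneg
chr6	7000000	13000000	p24	gpos
chr6	13000000	15000000	p23	gneg
chr6	15000000	30000000	p22	gpos
chr6	30000000	46000000	p21	gneg
chr6	46000000	57000000	p12	gpos
chr6	57000000	61000000	p11	acen
chr6	61000000	63000000	q11	acen
chr6	63000000	70000000	q12	gneg
chr6	70000000	76000000	q13	gpos
chr6	76000000	84000000	q14	gneg
chr6	84000000	93000000	q15	gpos
chr6	93000000	99000000	q16.1	gneg
chr6	99000000	100000000	q16.2	gpos
chr6	100000000	105000000	q16.3	gneg
chr6	105000000	114000000	q21	gpos
chr6	114000000	126000000	q22	gneg
chr6	126000000	136000000	q23	gpos
chr6	136000000	148000000	q24	gneg
chr6	148000000	161000000	q25	gpos
chr6	161000000	164000000	q26	gneg
chr6	164000000	171115067	q27	gpos
chr12	0	3300000	p13.33	gneg
chr12	3300000	5400000	p13.32	gpos
chr12	5400000	10000000	p13.31	gneg
chr12	10000000	12800000	p13.2	gpos
chr12	12800000	14800000	p13.1	gneg
chr12	14800000	19900000	p12.3	gpos
chr12	19900000	21300000	p12.2	gneg
chr12	21300000	26300000	p12.1	gpos
chr12	26300000	30700000	p11.2	gneg
chr12	30700000	35500000	p11.1	acen
chr12	35500000	38000000	q11	acen
chr12	38000000	46000000	q12	gneg
chr12	46000000	57000000	q13	gpos
chr12	57000000	67000000	q14	gneg
chr12	67000000	71000000	q15	gpos
chr12	71000000	89000000	q21	gneg
chr12	89000000	92000000	q22	gpos
chr12	92000000	108000000	q23	gneg
chr12	108000000	133851895	q24	gpos
chr13	0	4500000	p13	gvar
chr13	4500000	10000000	p12	stalk
chr13	10000000	17900000	p11	acen
chr13	17900000	19500000	q11	acen
chr13	19500000	33000000	q12	gneg
chr13	33000000	40000000	q13	gpos
chr13	40000000	50000000	q14	gneg
chr13	50000000	65000000	q21	gpos
chr13	65000000	74000000	q22	gneg
chr13	74000000	89000000	q31	gpos
chr13	89000000	98000000	q32	gneg
chr13	98000000	110000000	q33	gpos
chr13	110000000	115169878	q34	gneg
chr16	0	7900000	p13.3	gneg
chr16	7900000	10500000	p13.2	gpos
chr16	10500000	16800000	p13.1	gneg
chr16	16800000	21200000	p12.3	gpos
chr16	21200000	24200000	p12.2	gneg
chr16	24200000	28100000	p12.1	gpos
chr16	28100000	34600000	p11.2	gneg
chr16	34600000	36600000	p11.1	acen
chr16	36600000	38200000	q11	acen
chr16	38200000	47000000	q12	gneg
chr16	47000000	52600000	q13	gpos
chr16	52600000	56700000	q21	gneg
chr16	56700000	65500000	q22	gpos
chr16	65500000	74000000	q23	gneg
chr16	74000000	90354753	q24	gpos
chr18	0	8000000	p11.3	gneg
chr18	8000000	15400000	p11.2	gpos
chr18	15400000	17200000	p11.1	acen
chr18	17200000	25000000	q11	acen
chr18	25000000	43500000	q12	gneg
chr18	43500000	61000000	q21	gpos
chr18	61000000	73000000	q22	gneg
chr18	73000000	78077248	q23	gpos
chr21	0	2900000	p13	gvar
chr21	2900000	6800000	p12	stalk
chr21	6800000	13200000	p11	acen
chr21	13200000	15300000	q11	acen
chr21	15300000	31000000	q21	gneg
chr21	31000000	48129895	q22	gpos
chr22	0	3800000	p13	gvar
chr22	3800000	8300000	p12	stalk
chr22	8300000	14700000	p11	acen
chr22	14700000	22200000	q11	acen
chr22	22200000	32200000	q12	gneg
chr22	32200000	51304566	q13	gpos
chrX	0	37600000	p22	gneg
chrX	37600000	58100000	p21	gpos
chrX	58100000	60600000	p11	acen
chrX	60600000	63000000	q11	acen
chrX	63000000	64600000	q12	gneg
chrX	64600000	76000000	q13	gpos
chrX	76000000	92400000	q21	gneg
chrX	92400000	108000000	q22	gpos
chrX	108000000	115000000	q23	gneg
chrX	115000000	124000000	q24	gpos
chrX	124000000	129000000	q25	gneg
chrX	129000000	138000000	q26	gpos
chrX	138000000	147000000	q27	gneg
chrX	147000000	155270560	q28	gpos
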