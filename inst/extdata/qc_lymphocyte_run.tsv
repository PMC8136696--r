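sample	raw_reads	gc_pct	hq_of_raw	mapping_rate	mapped_of_raw	unique_of_raw
1	1514213	40	96.04	94.86	91.1	84.03
2	1616350	40	95.79	94.09	90.14	83.02
3	1837612	40	96.07	94.65	90.93	83.83
4	1495434	40	96.12	93.71	90.07	82.98
5	2381030	40	96.32	95	91.51	84.36
6	1944712	40	96.28	94.85	91.32	84.22
7	1992210	40	96.27	93.99	90.48	83.46
8	2174977	40	96.7	95.64	92.48	85.49
9	1700875	40	96.46	94.65	91.31	84.43
10	1567411	40	96.06	94.62	90.9	83.99
11	1505962	40	96.18	94.24	90.64	83.83
12	2110626	40	96.24	94.85	91.28	84.3
13	1481780	41	96.09	89.85	86.34	79.84
14	1888895	40	96.14	93.62	90.01	83.1
15	1389200	40	95.88	94.47	90.58	83.71
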