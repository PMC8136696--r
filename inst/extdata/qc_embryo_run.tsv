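sample	raw_reads	gc_pct	hq_of_raw	mapping_rate	mapped_of_raw	unique_reads	unique_of_raw
1	765904	41	97.11	97.17	94.36	621999	81.21
2	569266	41	97.35	97.43	94.85	457252	80.32
3	1151433	42	97.62	97.87	95.53	954220	82.87
4	848321	41	97.39	96.82	94.29	680302	80.19
5	1013240	41	97.31	97.32	94.70	823884	81.31
6	724464	41	97.38	97.03	94.48	585789	80.86
7	860599	41	97.28	97.61	94.96	709675	82.46
8	759668	42	97.47	97.05	94.59	619175	81.51
9	818820	41	97.15	97.67	94.88	676557	82.63
10	541819	42	97.59	97.60	95.26	439336	81.09
11	1018913	42	97.45	97.78	95.28	837823	82.23
12	813351	41	97.41	97.25	94.73	657646	80.86
13	1420866	41	97.25	90.75	88.25	1086243	76.45
14	899714	42	97.18	96.31	93.60	732360	81.40
NC	33236	43	90.89	57.68	52.43	15001	45.13
PC	959591	41	97.62	95.13	92.87	764751	79.70
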