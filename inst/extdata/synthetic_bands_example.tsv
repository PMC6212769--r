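strain	plasmid	passage	intensity_C	intensity_C1
wt	pCas1-2	1	92	8
wt	pBad	1	99	1
wt	pCas1-2	2	78	22
wt	pBad	2	98	2
wt	pCas1-2	3	64	36
wt	pBad	3	97	3
recB1080	pCas1-2	1	97	3
recB1080	pBad	1	99	1
recB1080	pCas1-2	2	93	7
recB1080	pBad	2	99	1
recB1080	pCas1-2	3	88	12
recB1080	pBad	3	98	2
recD_recA	pCas1-2	1	99	1
recD_recA	pBad	1	100	0
recD_recA	pCas1-2	2	98	2
recD_recA	pBad	2	99	1
recD_recA	pCas1-2	3	97	3
recD_recA	pBad	3	99	1
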