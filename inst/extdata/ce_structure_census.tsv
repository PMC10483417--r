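family	total_cazymes	with_pdb
CE0	2960	7
CE1	5026	6
CE2	709	4
CE3	600	3
CE4	34194	27
CE5	4195	10
CE6	453	1
CE7	2664	5
CE8	8927	7
CE9	19773	7
CE10	0	0
CE11	13842	4
CE12	3452	3
CE13	484	0
CE14	6487	6
CE15	583	8
CE16	189	0
CE17	18	1
CE18	37	1
CE19	251	1
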