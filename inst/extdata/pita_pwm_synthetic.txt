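# synthetic 15-bp zinc-finger-style binding-site count matrix (not the published one)
A	C	G	T
60	19	8	13
70	10	13	7
80	12	6	2
80	7	6	7
6	80	9	5
5	2	3	90
0	90	7	3
11	60	18	11
70	9	10	11
15	7	8	70
5	3	90	2
11	9	10	70
13	16	60	11
4	4	2	90
90	2	4	4
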