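graph	from	to
1	1	2
1	1	3
1	1	4
2	1	3
2	1	4
2	1	5
2	2	3
2	2	4
2	2	5
2	3	4
3	1	2
3	1	3
3	1	4
3	1	5
3	2	3
3	2	4
3	2	5
3	3	4
3	3	5
4	1	3
4	1	4
4	1	6
4	2	3
4	2	4
4	2	5
4	3	4
5	1	4
5	1	5
5	1	6
5	2	3
5	2	6
5	3	4
5	3	5
5	4	5
6	1	2
6	1	3
6	1	6
6	2	3
6	2	4
6	2	5
6	3	4
6	3	5
6	4	5
7	1	2
7	1	3
7	1	4
7	1	6
7	2	3
7	2	6
7	3	4
7	3	5
7	4	5
8	1	2
8	1	3
8	1	4
8	1	5
8	1	6
8	2	5
8	2	6
8	3	4
8	3	6
8	4	5
9	1	2
9	1	3
9	1	4
9	1	5
9	1	6
9	2	3
9	2	4
9	2	5
9	2	6
9	3	6
9	4	5
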