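distance_from_3prime	factor
1	100
2	80
3	60
4	45
5	30
6	20
7	15
8	12
9	10
10	8
11	6
12	5.5
13	5
14	4.5
15	4
16	3.5
17	3
18	2.5
19	2
20	2
21	2
22	2
23	2
24	2
25	2
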