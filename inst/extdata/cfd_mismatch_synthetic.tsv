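position	guide_base	genome_base	penalty
1	A	C	0.56
1	A	G	0.92
1	A	T	0.56
1	C	A	0.56
1	C	G	0.56
1	C	T	0.92
1	G	A	0.92
1	G	C	0.56
1	G	T	0.56
1	T	A	0.56
1	T	C	0.92
1	T	G	0.56
2	A	C	0.533
2	A	G	0.875
2	A	T	0.533
2	C	A	0.533
2	C	G	0.533
2	C	T	0.875
2	G	A	0.875
2	G	C	0.533
2	G	T	0.533
2	T	A	0.533
2	T	C	0.875
2	T	G	0.533
3	A	C	0.506
3	A	G	0.83
3	A	T	0.506
3	C	A	0.506
3	C	G	0.506
3	C	T	0.83
3	G	A	0.83
3	G	C	0.506
3	G	T	0.506
3	T	A	0.506
3	T	C	0.83
3	T	G	0.506
4	A	C	0.479
4	A	G	0.785
4	A	T	0.479
4	C	A	0.479
4	C	G	0.479
4	C	T	0.785
4	G	A	0.785
4	G	C	0.479
4	G	T	0.479
4	T	A	0.479
4	T	C	0.785
4	T	G	0.479
5	A	C	0.452
5	A	G	0.74
5	A	T	0.452
5	C	A	0.452
5	C	G	0.452
5	C	T	0.74
5	G	A	0.74
5	G	C	0.452
5	G	T	0.452
5	T	A	0.452
5	T	C	0.74
5	T	G	0.452
6	A	C	0.425
6	A	G	0.695
6	A	T	0.425
6	C	A	0.425
6	C	G	0.425
6	C	T	0.695
6	G	A	0.695
6	G	C	0.425
6	G	T	0.425
6	T	A	0.425
6	T	C	0.695
6	T	G	0.425
7	A	C	0.398
7	A	G	0.65
7	A	T	0.398
7	C	A	0.398
7	C	G	0.398
7	C	T	0.65
7	G	A	0.65
7	G	C	0.398
7	G	T	0.398
7	T	A	0.398
7	T	C	0.65
7	T	G	0.398
8	A	C	0.371
8	A	G	0.605
8	A	T	0.371
8	C	A	0.371
8	C	G	0.371
8	C	T	0.605
8	G	A	0.605
8	G	C	0.371
8	G	T	0.371
8	T	A	0.371
8	T	C	0.605
8	T	G	0.371
9	A	C	0.344
9	A	G	0.56
9	A	T	0.344
9	C	A	0.344
9	C	G	0.344
9	C	T	0.56
9	G	A	0.56
9	G	C	0.344
9	G	T	0.344
9	T	A	0.344
9	T	C	0.56
9	T	G	0.344
10	A	C	0.317
10	A	G	0.515
10	A	T	0.317
10	C	A	0.317
10	C	G	0.317
10	C	T	0.515
10	G	A	0.515
10	G	C	0.317
10	G	T	0.317
10	T	A	0.317
10	T	C	0.515
10	T	G	0.317
11	A	C	0.29
11	A	G	0.47
11	A	T	0.29
11	C	A	0.29
11	C	G	0.29
11	C	T	0.47
11	G	A	0.47
11	G	C	0.29
11	G	T	0.29
11	T	A	0.29
11	T	C	0.47
11	T	G	0.29
12	A	C	0.263
12	A	G	0.425
12	A	T	0.263
12	C	A	0.263
12	C	G	0.263
12	C	T	0.425
12	G	A	0.425
12	G	C	0.263
12	G	T	0.263
12	T	A	0.263
12	T	C	0.425
12	T	G	0.263
13	A	C	0.236
13	A	G	0.38
13	A	T	0.236
13	C	A	0.236
13	C	G	0.236
13	C	T	0.38
13	G	A	0.38
13	G	C	0.236
13	G	T	0.236
13	T	A	0.236
13	T	C	0.38
13	T	G	0.236
14	A	C	0.209
14	A	G	0.335
14	A	T	0.209
14	C	A	0.209
14	C	G	0.209
14	C	T	0.335
14	G	A	0.335
14	G	C	0.209
14	G	T	0.209
14	T	A	0.209
14	T	C	0.335
14	T	G	0.209
15	A	C	0.182
15	A	G	0.29
15	A	T	0.182
15	C	A	0.182
15	C	G	0.182
15	C	T	0.29
15	G	A	0.29
15	G	C	0.182
15	G	T	0.182
15	T	A	0.182
15	T	C	0.29
15	T	G	0.182
16	A	C	0.155
16	A	G	0.245
16	A	T	0.155
16	C	A	0.155
16	C	G	0.155
16	C	T	0.245
16	G	A	0.245
16	G	C	0.155
16	G	T	0.155
16	T	A	0.155
16	T	C	0.245
16	T	G	0.155
17	A	C	0.128
17	A	G	0.2
17	A	T	0.128
17	C	A	0.128
17	C	G	0.128
17	C	T	0.2
17	G	A	0.2
17	G	C	0.128
17	G	T	0.128
17	T	A	0.128
17	T	C	0.2
17	T	G	0.128
18	A	C	0.101
18	A	G	0.155
18	A	T	0.101
18	C	A	0.101
18	C	G	0.101
18	C	T	0.155
18	G	A	0.155
18	G	C	0.101
18	G	T	0.101
18	T	A	0.101
18	T	C	0.155
18	T	G	0.101
19	A	C	0.074
19	A	G	0.11
19	A	T	0.074
19	C	A	0.074
19	C	G	0.074
19	C	T	0.11
19	G	A	0.11
19	G	C	0.074
19	G	T	0.074
19	T	A	0.074
19	T	C	0.11
19	T	G	0.074
20	A	C	0.047
20	A	G	0.065
20	A	T	0.047
20	C	A	0.047
20	C	G	0.047
20	C	T	0.065
20	G	A	0.065
20	G	C	0.047
20	G	T	0.047
20	T	A	0.047
20	T	C	0.065
20	T	G	0.047
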