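# BHC1
1 2
2 3
3 4
4 5
5 6
6 7
7 8
8 9
9 10
10 1
5 10
# BHC2
1 2
2 3
3 4
4 5
5 6
6 1
5 7
7 8
8 9
9 10
10 6
9 11
11 12
12 13
13 14
14 10
# BHC3
1 2
2 3
3 4
4 5
5 6
6 1
5 7
7 8
8 9
9 10
10 6
8 11
11 12
12 13
13 14
14 9
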