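# C8:01
1 2
2 3
3 4
4 5
5 6
6 7
7 8
# C8:02
1 2
2 3
3 4
4 5
5 6
6 7
2 8
# C8:03
1 2
2 3
3 4
4 5
5 6
6 7
3 8
# C8:04
1 2
2 3
3 4
4 5
5 6
6 7
4 8
# C8:05
1 2
2 3
3 4
4 5
5 6
3 7
7 8
# C8:06
1 2
2 3
3 4
4 5
5 6
2 7
2 8
# C8:07
1 2
2 3
3 4
4 5
5 6
2 7
3 8
# C8:08
1 2
2 3
3 4
4 5
5 6
2 7
4 8
# C8:09
1 2
2 3
3 4
4 5
5 6
2 7
5 8
# C8:10
1 2
2 3
3 4
4 5
5 6
3 7
3 8
# C8:11
1 2
2 3
3 4
4 5
5 6
3 7
4 8
# C8:12
1 2
2 3
3 4
4 5
2 6
3 7
7 8
# C8:13
1 2
2 3
3 4
4 5
3 6
3 7
7 8
# C8:14
1 2
2 3
3 4
4 5
2 6
2 7
3 8
# C8:15
1 2
2 3
3 4
4 5
2 6
2 7
4 8
# C8:16
1 2
2 3
3 4
4 5
2 6
3 7
3 8
# C8:17
1 2
2 3
3 4
4 5
2 6
3 7
4 8
# C8:18
1 2
2 3
3 4
2 5
2 6
3 7
3 8
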