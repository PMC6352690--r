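specimen,shore0010_partA,shore0010_partB,shore30A_partA,shore30A_partB
1,45,45,5,5
2,45,45,5,5
3,15,15,35,35
4,42,42,8,8
5,42,42,8,8
6,35,35,15,15
7,12.5,12.5,37.5,37.5
8,12.5,12.5,37.5,37.5
9,10,10,40,40
10,15,15,35,35
11,15,15,35,35
12,45,45,5,5
13,42,42,8,8
14,25,25,25,25
15,5,5,45,45
16,3,3,47,47
17,3,3,57,37
18,3,3,47,47
19,5,5,45,45
20,5,5,47,43
21,3,3,54,40
22,3,3,52,42
23,4,4,46,46
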