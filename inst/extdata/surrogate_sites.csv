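sample_location,shore0010_partA,shore0010_partB,shore30A_partA,shore30A_partB,c1_MPa,c2
1,3,7,51,39,27,0.29
2,8,2,44,46,16,0.26
3,7,3,61,29,35,0.33
4,4,6,52,38,28,0.3
5,7,3,45,45,15,0.23
6,5,5,45,45,13.1,0.21
7,2,8,48,42,18,0.2
8,5,5,47,43,22,0.26
9,6,4,58,32,33,0.3
10,8,2,42,48,14.4,0.27
11,7,3,48,42,24,0.28
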