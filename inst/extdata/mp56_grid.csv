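"index","x_deg","y_deg"
0,-0.7,-0.7
1,0.7,-0.7
2,0.7,0.7
3,-0.7,0.7
4,-2.1,-0.7
5,-0.7,-2.1
6,0.7,-2.1
7,2.1,-0.7
8,2.1,0.7
9,0.7,2.1
10,-0.7,2.1
11,-2.1,0.7
12,-2.1,-2.1
13,2.1,-2.1
14,2.1,2.1
15,-2.1,2.1
16,-3.5,-0.7
17,-0.7,-3.5
18,0.7,-3.5
19,3.5,-0.7
20,3.5,0.7
21,0.7,3.5
22,-0.7,3.5
23,-3.5,0.7
24,-3.5,-2.1
25,3.5,-2.1
26,3.5,2.1
27,-3.5,2.1
28,-4.2,-1.4
29,-1.4,-4.2
30,1.4,-4.2
31,4.2,-1.4
32,4.2,1.4
33,1.4,4.2
34,-1.4,4.2
35,-4.2,1.4
36,-4.2,-4.2
37,4.2,-4.2
38,4.2,4.2
39,-4.2,4.2
40,-7,-1.4
41,-1.4,-7
42,1.4,-7
43,7,-1.4
44,7,1.4
45,1.4,7
46,-1.4,7
47,-7,1.4
48,-7,-4.2
49,-4.2,-7
50,4.2,-7
51,7,-4.2
52,7,4.2
53,4.2,7
54,-4.2,7
55,-7,4.2
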