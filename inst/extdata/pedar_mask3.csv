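# Approximate template region table for the bundled 99-sensor insole layout.
# Editable: sensor numbers follow the bundled layout (1 = medial heel).
sensor,region
1,heel
2,heel
3,heel
4,heel
5,heel
6,heel
7,heel
8,heel
9,heel
10,heel
11,heel
12,heel
13,heel
14,heel
15,heel
16,heel
17,heel
18,heel
19,heel
20,heel
21,heel
22,heel
23,heel
24,heel
25,heel
26,heel
27,midfoot
28,midfoot
29,midfoot
30,midfoot
31,midfoot
32,midfoot
33,midfoot
34,midfoot
35,midfoot
36,midfoot
37,midfoot
38,midfoot
39,midfoot
40,midfoot
41,midfoot
42,midfoot
43,midfoot
44,midfoot
45,midfoot
46,midfoot
47,midfoot
48,midfoot
49,midfoot
50,midfoot
51,midfoot
52,midfoot
53,midfoot
54,midfoot
55,MTH1
56,MTH1
57,MTH2
58,MTH3
59,MTH4
60,MTH5
61,MTH5
62,MTH1
63,MTH1
64,MTH2
65,MTH3
66,MTH4
67,MTH5
68,MTH5
69,MTH1
70,MTH1
71,MTH2
72,MTH3
73,MTH4
74,MTH5
75,MTH5
76,MTH1
77,MTH1
78,MTH2
79,MTH3
80,MTH4
81,MTH5
82,MTH5
83,MTH1
84,MTH1
85,MTH2
86,MTH3
87,MTH4
88,MTH5
89,MTH5
90,hallux
91,hallux
92,toe2
93,toes3_5
94,toes3_5
95,hallux
96,hallux
97,toe2
98,toes3_5
99,toes3_5
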