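# Approximate template region table for the bundled 99-sensor insole layout.
# Editable: sensor numbers follow the bundled layout (1 = medial heel).
sensor,region
1,rearfoot
2,rearfoot
3,rearfoot
4,rearfoot
5,rearfoot
6,rearfoot
7,rearfoot
8,rearfoot
9,rearfoot
10,rearfoot
11,rearfoot
12,rearfoot
13,rearfoot
14,rearfoot
15,rearfoot
16,rearfoot
17,rearfoot
18,rearfoot
19,rearfoot
20,rearfoot
21,rearfoot
22,rearfoot
23,rearfoot
24,rearfoot
25,rearfoot
26,rearfoot
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
55,forefoot
56,forefoot
57,forefoot
58,forefoot
59,forefoot
60,forefoot
61,forefoot
62,forefoot
63,forefoot
64,forefoot
65,forefoot
66,forefoot
67,forefoot
68,forefoot
69,forefoot
70,forefoot
71,forefoot
72,forefoot
73,forefoot
74,forefoot
75,forefoot
76,forefoot
77,forefoot
78,forefoot
79,forefoot
80,forefoot
81,forefoot
82,forefoot
83,forefoot
84,forefoot
85,forefoot
86,forefoot
87,forefoot
88,forefoot
89,forefoot
90,forefoot
91,forefoot
92,forefoot
93,forefoot
94,forefoot
95,forefoot
96,forefoot
97,forefoot
98,forefoot
99,forefoot
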