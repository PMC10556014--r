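# Approximate template region table for the bundled 99-sensor insole layout.
# Editable: sensor numbers follow the bundled layout (1 = medial heel).
sensor,region
1,heel_medial
2,heel_medial
3,heel_medial
4,heel_lateral
5,heel_lateral
6,heel_medial
7,heel_medial
8,heel_medial
9,heel_medial
10,heel_lateral
11,heel_lateral
12,heel_lateral
13,heel_medial
14,heel_medial
15,heel_medial
16,heel_medial
17,heel_lateral
18,heel_lateral
19,heel_lateral
20,heel_medial
21,heel_medial
22,heel_medial
23,heel_medial
24,heel_lateral
25,heel_lateral
26,heel_lateral
27,midfoot_medial
28,midfoot_medial
29,midfoot_medial
30,midfoot_medial
31,midfoot_lateral
32,midfoot_lateral
33,midfoot_lateral
34,midfoot_medial
35,midfoot_medial
36,midfoot_medial
37,midfoot_medial
38,midfoot_lateral
39,midfoot_lateral
40,midfoot_lateral
41,midfoot_medial
42,midfoot_medial
43,midfoot_medial
44,midfoot_medial
45,midfoot_lateral
46,midfoot_lateral
47,midfoot_lateral
48,midfoot_medial
49,midfoot_medial
50,midfoot_medial
51,midfoot_medial
52,midfoot_lateral
53,midfoot_lateral
54,midfoot_lateral
55,forefoot_medial
56,forefoot_medial
57,forefoot_central
58,forefoot_central
59,forefoot_central
60,forefoot_lateral
61,forefoot_lateral
62,forefoot_medial
63,forefoot_medial
64,forefoot_central
65,forefoot_central
66,forefoot_central
67,forefoot_lateral
68,forefoot_lateral
69,forefoot_medial
70,forefoot_medial
71,forefoot_central
72,forefoot_central
73,forefoot_central
74,forefoot_lateral
75,forefoot_lateral
76,forefoot_medial
77,forefoot_medial
78,forefoot_central
79,forefoot_central
80,forefoot_central
81,forefoot_lateral
82,forefoot_lateral
83,forefoot_medial
84,forefoot_medial
85,forefoot_central
86,forefoot_central
87,forefoot_central
88,forefoot_lateral
89,forefoot_lateral
90,hallux
91,hallux
92,lesser_toes
93,lesser_toes
94,lesser_toes
95,hallux
96,hallux
97,lesser_toes
98,lesser_toes
99,lesser_toes
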