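rs,t,pr_n,pr_cl
12,1.9,0,0
13,3.9,0,0
14,5.7,NA,0
15,7.4,NA,0
16,9.0,NA,0
17,10.5,NA,1
18,11.9,0,1
19,13.2,NA,1
20,14.4,0,1
21,15.6,NA,2
22,16.7,NA,2
23,17.7,NA,2
24,18.7,0,3
25,19.6,0,3
26,20.5,0,4
27,21.3,0,5
28,22.1,0,6
29,22.9,0,6
30,23.6,0,7
31,24.4,0,8
32,25.0,0,10
33,25.7,1,11
34,26.4,1,12
35,27.0,1,13
36,27.7,1,15
37,28.3,1,17
38,28.9,1,19
39,29.6,2,21
40,30.2,2,23
41,30.8,2,25
42,31.5,3,27
43,32.1,3,29
44,32.8,4,31
45,33.5,5,34
46,34.1,5,36
47,34.8,6,39
48,35.6,8,41
49,36.3,9,44
50,37.0,10,46
51,37.8,12,49
52,38.6,14,51
53,39.4,16,54
54,40.2,18,56
55,41.1,20,59
56,42.0,23,61
57,42.9,26,63
58,43.8,29,65
59,44.8,33,67
60,45.8,37,70
61,46.8,41,72
62,47.9,45,74
63,48.9,50,77
64,50.1,55,79
65,51.2,60,81
66,52.4,65,83
67,53.6,70,85
68,54.8,75,87
69,56.1,79,89
70,57.4,84,90
71,58.8,88,92
72,60.2,91,94
73,61.7,94,95
74,63.2,96,96
75,64.7,97,97
76,66.3,98,98
77,67.9,99,98
78,69.6,99,99
79,71.3,100,99
80,73.1,100,99
81,75.0,100,100
82,76.9,100,100
83,78.8,100,100
84,80.9,100,100
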