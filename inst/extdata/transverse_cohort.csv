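patient_id,mla_deg,outcome,aida_mla,aida_aop,aida_spd,aida_ad,aida_class,pred_svm,pred_rf,pred_mlp
116,76,ICD,RED,GREEN,GREEN,RED,2,ICD,ICD,NOICD
128,76,NOICD,RED,GREEN,GREEN,YELLOW,2,ICD,ICD,ICD
76,77,ICD,RED,GREEN,GREEN,RED,2,ICD,ICD,ICD
65,82,ICD,RED,GREEN,RED,GREEN,2,ICD,ICD,ICD
110,75,ICD,RED,RED,GREEN,RED,3,ICD,ICD,ICD
12,77,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
50,77,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
7,78,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
9,81,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
63,81,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
10,84,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
24,86,NOICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
11,86,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
94,88,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
20,88,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
43,88,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
118,88,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
52,88,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
46,90,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
28,90,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
18,75,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
71,78,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
85,79,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
60,79,ICD,RED,RED,RED,YELLOW,4,ICD,ICD,ICD
4,81,ICD,RED,RED,RED,YELLOW,4,ICD,ICD,ICD
83,83,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
13,84,ICD,RED,RED,RED,YELLOW,4,ICD,ICD,ICD
114,87,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
78,89,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
101,71,ICD,RED,GREEN,GREEN,RED,2,ICD,ICD,ICD
8,72,ICD,RED,RED,GREEN,GREEN,2,ICD,ICD,ICD
91,73,ICD,RED,GREEN,GREEN,RED,2,ICD,ICD,ICD
42,70,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
26,71,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
51,72,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
122,70,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
69,74,ICD,RED,RED,RED,YELLOW,4,ICD,ICD,ICD
84,74,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
104,60,NOICD,GREEN,GREEN,GREEN,GREEN,0,NOICD,NOICD,NOICD
53,64,ICD,RED,GREEN,GREEN,GREEN,1,ICD,NOICD,ICD
112,67,NOICD,RED,GREEN,GREEN,GREEN,1,NOICD,NOICD,ICD
25,64,ICD,RED,GREEN,RED,GREEN,2,ICD,ICD,ICD
113,66,ICD,RED,GREEN,RED,GREEN,2,NOICD,ICD,NOICD
55,68,ICD,RED,RED,GREEN,GREEN,2,ICD,ICD,ICD
44,61,ICD,YELLOW,RED,RED,GREEN,3,ICD,ICD,ICD
57,61,ICD,YELLOW,RED,RED,GREEN,3,ICD,ICD,ICD
115,64,NOICD,RED,RED,GREEN,RED,3,ICD,NOICD,ICD
33,64,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
77,67,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
100,67,NOICD,RED,RED,GREEN,RED,3,ICD,ICD,ICD
39,67,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
126,68,ICD,RED,RED,GREEN,RED,3,ICD,ICD,ICD
64,68,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
29,68,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
96,69,ICD,RED,RED,RED,GREEN,3,ICD,ICD,ICD
99,69,ICD,RED,GREEN,RED,RED,3,ICD,ICD,ICD
135,69,ICD,RED,RED,GREEN,RED,3,ICD,ICD,NOICD
2,61,ICD,YELLOW,RED,RED,YELLOW,4,ICD,ICD,ICD
74,64,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
93,65,ICD,RED,RED,RED,RED,4,ICD,ICD,NOICD
102,65,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
22,66,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
121,66,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
117,67,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
70,68,ICD,RED,RED,RED,YELLOW,4,ICD,ICD,ICD
67,68,ICD,RED,RED,RED,RED,4,ICD,ICD,ICD
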