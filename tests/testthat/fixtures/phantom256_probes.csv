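row,col,value
211,189,1
117,89,0
122,227,5.55111512313e-17
64,223,5.55111512313e-17
194,199,1
151,197,0.2
25,53,5.55111512313e-17
31,164,0.2
234,99,0.2
72,234,5.55111512313e-17
14,217,5.55111512313e-17
73,98,0.2
60,42,5.55111512313e-17
256,27,5.55111512313e-17
2,247,5.55111512313e-17
228,40,5.55111512313e-17
201,13,5.55111512313e-17
223,8,5.55111512313e-17
66,93,0.2
126,76,0.2
207,143,0.2
207,170,0.2
50,65,1
15,237,5.55111512313e-17
15,115,1
256,174,5.55111512313e-17
111,30,5.55111512313e-17
92,93,0
220,112,0.2
51,112,0.2
223,208,5.55111512313e-17
206,102,0.2
18,88,5.55111512313e-17
51,254,5.55111512313e-17
152,30,5.55111512313e-17
176,39,5.55111512313e-17
175,56,0.2
15,180,5.55111512313e-17
119,146,0
253,123,5.55111512313e-17
213,5,5.55111512313e-17
46,225,5.55111512313e-17
190,35,5.55111512313e-17
188,99,0.2
85,25,5.55111512313e-17
77,38,5.55111512313e-17
133,134,0.2
114,251,5.55111512313e-17
135,167,0
35,157,0.2
256,211,5.55111512313e-17
239,167,5.55111512313e-17
64,238,5.55111512313e-17
191,175,0.2
56,33,5.55111512313e-17
187,34,5.55111512313e-17
54,185,0.2
98,107,0.1
105,247,5.55111512313e-17
207,237,5.55111512313e-17
51,5,5.55111512313e-17
115,25,5.55111512313e-17
170,182,0.2
11,214,5.55111512313e-17
84,75,0.2
191,96,0.2
134,20,5.55111512313e-17
181,206,1
203,69,0.2
133,71,0.2
143,9,5.55111512313e-17
139,121,0
66,25,5.55111512313e-17
199,199,5.55111512313e-17
1,109,5.55111512313e-17
161,141,0
123,229,5.55111512313e-17
215,125,0.2
207,219,5.55111512313e-17
36,13,5.55111512313e-17
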