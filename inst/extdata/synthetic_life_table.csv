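age,qx
40,0.00123752207841921
41,0.00131915395561533
42,0.00140981552687969
43,0.00151050464846481
44,0.00162232922336625
45,0.00174651928511371
46,0.00188444039614877
47,0.00203760850091605
48,0.00220770638805678
49,0.00239660193162927
50,0.00260636829819072
51,0.00283930632490537
52,0.0030979692936649
53,0.00338519034755436
54,0.00370411281888361
55,0.00405822376241605
56,0.0044513910133025
57,0.00488790411644613
58,0.00537251950238182
59,0.00591051031397438
60,0.00650772131786881
61,0.00717062936412249
62,0.00790640988598179
63,0.00872300995834585
64,0.0096292284566859
65,0.0106348038763613
66,0.0117505103831258
67,0.0129882626663703
68,0.0143612301537346
69,0.0158839611147467
70,0.01757251712665
71,0.019444618290804
72,0.0215197994648044
73,0.0238195776036904
74,0.0263676300712798
75,0.029189983475212
76,0.0323152121795277
77,0.0357746451361369
78,0.0396025790276486
79,0.0438364949012712
80,0.0485172744656622
81,0.0536894109848237
82,0.059401208197157
83,0.0657049588732155
84,0.0726570924610457
85,0.0803182787141694
86,0.0887534712205046
87,0.0980318713292936
88,0.108226789105234
89,0.119415373653914
90,0.131678180535233
91,0.145098539152644
92,0.15976167820575
93,0.175753562872783
94,0.193159393852361
95,0.212061716440241
96,0.232538088379598
97,0.25465825950719
98,0.278480825720869
99,0.304049336306132
100,1
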