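# source: fixture
# synthetic Gompertz background mortality, qx = min(1, 2.3e-5 * exp(0.095 * age))
"age","qx"
0,2.3e-05
1,2.52921536679004e-05
2,2.78127407461168e-05
3,3.05845266467939e-05
4,3.36325455569872e-05
5,3.6984326542173e-05
6,4.06701421829759e-05
7,4.47232819907471e-05
8,4.91803530714268e-05
9,5.40816107532227e-05
10,5.94713221642645e-05
11,6.53981660439907e-05
12,7.19156723992816e-05
13,7.90827059762179e-05
14,8.6963997914082e-05
15,9.56307303833882e-05
16,0.00010516117948827
17,0.000115641422239781
18,0.000127166113985352
19,0.000139839343315968
20,0.000153775572172423
21,0.000169100669641488
22,0.000185953048779016
23,0.000204484916727542
24,0.000224863649419165
25,0.000247273303279756
26,0.000271916277587866
27,0.000299015142502425
28,0.000328814649269585
29,0.000361583940764483
30,0.000397618982333056
31,0.000437245234888774
32,0.000480820594407133
33,0.000528738624366801
34,0.000581432110332147
35,0.000639376968781402
36,0.000703096545484155
37,0.000773166342250224
38,0.000850219214740918
39,0.000934951088288212
40,0.00102812724334592
41,0.00113058922734173
42,0.00124326245535651
43,0.00136716456827861
44,0.00150341462392223
45,0.00165324320412216
46,0.00181800352908998
47,0.0019991836794143
48,0.00219842003609153
49,0.00241751205997469
50,0.00265843854412532
51,0.00292337548585595
52,0.00321471573988007
53,0.00353509063007238
54,0.00388739371503241
55,0.00427480692209694
56,0.00470082928583827
57,0.00516930855060816
58,0.00568447592255535
59,0.00625098428498911
60,0.00687395022224239
61,0.00755900023158488
62,0.00831232154056258
63,0.00914071798873509
64,0.010051671478523
65,0.0110534095501763
66,0.0121549796911868
67,0.0133663310512915
68,0.0146984043010997
69,0.0161632304459279
70,0.0177740394873084
71,0.0195453799135798
72,0.0214932500987718
73,0.0236352427965544
74,0.0259907040342865
75,0.0285809078422649
76,0.0314292483962897
77,0.0345614513089378
78,0.0380058059778831
79,0.0417934210897837
80,0.0459585055873947
81,0.0505386776375411
82,0.0555753043904856
83,0.0611138755993261
84,0.067204414473874
85,0.0739019294797603
86,0.0812669111633233
87,0.0893658784894949
88,0.0982719796270962
89,0.108065652607708
90,0.118835351825048
91,0.13067834693644
92,0.143701601381897
93,0.158022738455405
94,0.173771103653762
95,0.191088932897895
96,0.210132637177768
97,0.231074215223533
98,0.254102806961873
99,0.279426401788022
100,1
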