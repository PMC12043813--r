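age	sex	qx
0	male	0.00026728767193284764
1	male	0.00026992707614414968
2	male	0.00027282951231266672
3	male	0.00027602119221892263
4	male	0.00027953093952715058
5	male	0.00028339045000902452
6	male	0.00028763457768554712
7	male	0.00029230164946658643
8	male	0.00029743381112523615
9	male	0.00030307740772284042
10	male	0.00030928340191571646
11	male	0.00031610783390811914
12	male	0.00032361232719702038
13	male	0.00033186464465884136
14	male	0.00034093929998657568
15	male	0.0003509182299746838
16	male	0.00036189153370225213
17	male	0.00037395828525577102
18	male	0.00038722742729735415
19	male	0.00040181875350253637
20	male	0.00041786398868570718
21	male	0.00043550797630453886
22	male	0.00045490998398567406
23	male	0.00047624513877009278
24	male	0.00049970600492088568
25	male	0.00052550431840447942
26	male	0.00055387289354014158
27	male	0.00058506771883060082
28	male	0.000619370260654728
29	male	0.00065708999532620993
30	male	0.00069856719202232576
31	male	0.00074417597127740542
32	male	0.00079432766613130035
33	male	0.00084947451564476584
34	male	0.00091011372336258223
35	male	0.00097679191643751384
36	male	0.0010501100445499123
37	male	0.0011307287614934491
38	male	0.0012193743363680953
39	male	0.0013168451457591379
40	male	0.0014240188031072742
41	male	0.0015418599867252913
42	male	0.0016714290336106163
43	male	0.0018138913723860783
44	male	0.0019705278753797684
45	male	0.0021427462170819922
46	male	0.0023320933340029715
47	male	0.0025402690893261415
48	male	0.0027691412547378169
49	male	0.0030207619314159828
50	male	0.0032973855423883425
51	male	0.0036014885393309548
52	male	0.0039357909783253042
53	male	0.0043032801311220226
54	male	0.0047072363109793569
55	male	0.0051512611050895663
56	male	0.0056393082188301857
57	male	0.0061757171504183139
58	male	0.0067652499277685019
59	male	0.0074131311521576926
60	male	0.0081250916052960642
61	male	0.0089074156871022936
62	male	0.0097669929602619554
63	male	0.010711374083729797
64	male	0.011748831419776451
65	male	0.01288842459676931
66	male	0.014140071301197432
67	male	0.015514623555705986
68	male	0.017023949712984598
69	male	0.018681022355659938
70	male	0.020500012236797094
71	male	0.022496388320514926
72	male	0.024687023883207093
73	male	0.027090308507751848
74	male	0.029726265639847926
75	male	0.032616675170175746
76	male	0.035785200250305182
77	male	0.039257517234828843
78	male	0.043061447256513508
79	male	0.047227087473495466
80	male	0.051786939464628201
81	male	0.056776031576899144
82	male	0.062232031232420271
83	male	0.068195342266623937
84	male	0.074709181279128622
85	male	0.081819625720964351
86	male	0.089575625006207416
87	male	0.098028964317499967
88	male	0.10723416897643989
89	male	0.11724833528624612
90	male	0.12813087165701476
91	male	0.1399431316476808
92	male	0.15274791838827828
93	male	0.16660883780548563
94	male	0.18158947633792366
95	male	0.19775237763098985
96	male	0.21515779235384958
97	male	0.23386217617892435
98	male	0.25391641359737138
99	male	0.27536375020303583
100	male	0.29823742404807352
0	female	0.00018434397183686446
1	female	0.00018616440237007037
2	female	0.00018816625109940865
3	female	0.00019036759715418405
4	female	0.00019278832124092204
5	female	0.00019545028515255414
6	female	0.000198377529157856
7	female	0.00020159648905526684
8	female	0.0002051362348461927
9	female	0.00020902873318218163
10	female	0.00021330913595041245
11	female	0.00021801609760196961
12	female	0.00022319212407984068
13	female	0.0002288839564946743
14	female	0.00023514299300231301
15	female	0.00024202575268583715
16	female	0.00024959438561744651
17	female	0.00025791723369383845
18	female	0.00026706944729215643
19	female	0.0002771336632940713
20	female	0.00028820075057645056
21	female	0.00030037062966981054
22	female	0.0003137531739497712
23	female	0.00032846920045537242
24	female	0.00034465155922580593
25	female	0.00036244633092985534
26	female	0.00038201414352101448
27	female	0.00040353161971262708
28	female	0.00042719296822846253
29	female	0.00045321173305556961
30	female	0.00048182271632590812
31	female	0.00051328409198270197
32	female	0.00054787972906855664
33	female	0.00058592174531302277
34	female	0.00062775331370890086
35	female	0.00067375174698114382
36	female	0.00072433188726162001
37	female	0.00077994983092966041
38	female	0.00084110702146855676
39	female	0.0009083547463458741
40	female	0.00098229907737279465
41	female	0.0010636062977662508
42	female	0.0011530088632338842
43	female	0.001251311948880951
44	female	0.0013594006385928559
45	female	0.0014782478188447579
46	female	0.0016089228446186654
47	female	0.0017526010513391199
48	female	0.0019105741934650755
49	female	0.0020842618976483207
50	female	0.00227522422621107
51	female	0.0024851754551169503
52	female	0.0027159991796529281
53	female	0.0029697648706950019
54	female	0.0032487460147214708
55	female	0.0035554399816427606
56	female	0.0038925897760284656
57	female	0.0042632078393820549
58	female	0.0046706020836798645
59	female	0.0051184043493671671
60	female	0.0056106014942468585
61	female	0.0061515693330376209
62	female	0.0067461096605797577
63	female	0.0073994906044128061
64	female	0.0081174905643561779
65	female	0.0089064460072771912
66	female	0.0097733033938084413
67	female	0.010725675519576594
68	female	0.011771902555564484
69	female	0.012921118069326165
70	female	0.014183320299449576
71	female	0.015569448938110186
72	female	0.01709146764860825
73	female	0.018762452503813698
74	female	0.020596686474311898
75	female	0.02260976001800663
76	female	0.024818677721548887
77	female	0.027241970812983518
78	female	0.029899815198298874
79	female	0.03281415446498881
80	female	0.03600882703503383
81	female	0.03950969632845247
82	female	0.043344782406065652
83	female	0.047544393084408831
84	female	0.052141251943652156
85	female	0.057170619966723457
86	female	0.062670406739593232
87	female	0.068681266193615143
88	female	0.075246670766194401
89	female	0.082412956582743169
90	female	0.090229330810995378
91	female	0.09874783070381965
92	female	0.1080232220325682
93	female	0.11811282263585043
94	female	0.12907623470176344
95	female	0.14097496722180147
96	female	0.15387192788984205
97	female	0.16783076169799183
98	female	0.18291501178182301
99	female	0.19918707693249882
100	female	0.21670693993932633
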