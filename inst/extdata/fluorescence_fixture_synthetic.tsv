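time_s	F
0	104.11287534144
2	98.305905485811735
4	101.08938523401201
6	101.89858781488311
8	101.21280496942299
10	99.681626451725549
12	104.53456599231681
14	99.716022884760704
16	106.05527114163112
18	99.811857702842744
20	103.91460896267046
22	106.85993617810333
24	95.833417896662979
26	99.163633699547887
28	99.600035990819023
30	101.90785119421022
32	99.147241235751778
34	92.030633737285669
36	92.678599214273447
38	103.96034003719058
40	99.080084217764579
42	94.656074698059996
44	99.484247932721132
46	103.6440240975178
48	105.6855803837949
50	98.708592605181394
52	99.228191851693211
54	94.710510744415657
56	101.38029206449382
58	98.080015372119647
60	251.36635036972365
62	248.42632331591213
64	245.84984638196678
66	237.46743040282382
68	237.4718637622255
70	227.57816801297406
72	227.25383269613448
74	224.0348534303584
76	216.42431511618307
78	220.95041764737002
80	218.72776824015207
82	214.38389786407868
84	215.18549488610796
86	208.25862388144012
88	203.94267895996094
90	207.03315329533743
92	201.06352016631857
94	205.66634152482669
96	197.94697045273793
98	199.18413183843319
100	196.22520168677843
102	191.01432985389246
104	196.26152893197838
106	191.69158770775445
108	188.31879040298622
110	187.22195069892069
112	186.82728470539251
114	183.50858538055465
116	172.76031084825848
118	181.14388397688356
120	177.78473320356434
122	178.08532003004777
124	177.96277220445538
126	179.14720739791198
128	171.53842936956514
130	176.44049058652465
132	172.39189319937898
134	173.38900604860834
136	171.96123072805474
138	170.32246120492701
140	164.02532122231568
142	165.91192289315026
144	167.11271292942936
146	161.472092235292
148	161.82449655996177
150	164.34513250974342
152	164.08373309585639
154	162.37453289700446
156	157.5560293821697
158	156.16938312307107
160	163.28662634864048
162	158.82566076852873
164	157.64344583509589
166	156.36375307755429
168	152.5131382394469
170	157.32246212808673
172	154.24538522455157
174	153.77819954355067
176	156.57487135760044
178	155.70659923425956
180	156.90156849192172
182	150.79755553318222
184	153.69434474595081
186	155.44967954763047
188	147.49233912570921
190	147.80549218854384
192	146.57013927320125
194	145.17905036112731
196	149.40137462852036
198	150.73873293776299
200	152.01224251154105
202	151.18594873056426
204	144.69614380453936
206	152.91663052025135
208	145.04724865785352
210	147.05110378255682
212	145.16504973556474
214	145.771947061769
216	146.42035665261704
218	145.93932545153876
220	145.24161060996295
222	145.38483836704793
224	143.35644786330138
226	143.06036160051136
228	139.35783480559257
230	142.96985187915189
232	142.36197604030301
234	151.7957852573802
236	139.40082754455949
238	143.70266190961715
240	138.62016998943582
242	138.50611386432422
244	143.11392405860914
246	139.57811786462312
248	142.39641746733955
250	140.95640575051615
252	140.24473312821772
254	135.86137571138102
256	138.11575538546265
258	142.18790565599332
260	143.21618603483651
262	139.90311977190899
264	141.25468152273274
266	144.50007488366788
268	145.33192153456707
270	137.60586432979338
272	140.43387330608013
274	144.28260480390051
276	139.16473003362151
278	140.31573527624684
280	140.11735059102082
282	137.61835967419387
284	138.85615968241137
286	140.01368142984217
288	138.77510528664484
290	143.27436227604758
292	138.41142297488713
294	138.4777079398508
296	141.79314677833401
298	136.46124533463069
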