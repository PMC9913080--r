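age,rate
0,0.000308
1,0.000308885684882846
2,0.000309869424479654
3,0.000310962074487656
4,0.000312175692444949
5,0.000313523670787033
6,0.000315020884634115
7,0.00031668385594004
8,0.000318530935814249
9,0.000320582507028707
10,0.000322861208944505
11,0.000325392187340221
12,0.000328203371898923
13,0.000331325784415942
14,0.000334793881128502
15,0.000338645932944882
16,0.000342924447768976
17,0.000347676639580661
18,0.000352954949448345
19,0.000358817624223126
20,0.000365329359300541
21,0.000372562012542851
22,0.000380595397240109
23,0.000389518162860422
24,0.00039942877330862
25,0.000410436593488537
26,0.000422663096159258
27,0.00043624320240317
28,0.00045132677049804
29,0.000468080249623036
30,0.000486688516647542
31,0.000507356916271992
32,0.000530313527033941
33,0.000555811678185044
34,0.000584132745213028
35,0.000615589254857604
36,0.000650528333884592
37,0.000689335539675923
38,0.000732439114906613
39,0.000780314713259605
40,0.000833490648327401
41,0.000892553723622788
42,0.000958155708033613
43,0.00103102052817911
44,0.00111195225703636
45,0.00120184398699255
46,0.00130168768523812
47,0.00141258514025663
48,0.00153576012020713
49,0.0016725718773685
50,0.00182453014766904
51,0.00199331181082315
52,0.00218077939492191
53,0.00238900162967815
54,0.00262027627513388
55,0.00287715547774781
56,0.00316247393367082
57,0.00347938016999481
58,0.00383137128916776
59,0.00422233155998414
60,0.00465657528100743
61,0.00513889438942834
62,0.00567461134072875
63,0.00626963784268552
64,0.00693054009185176
65,0.00766461123240864
66,0.00847995183698108
67,0.00938555929753353
68,0.0103914271127864
69,0.0115086551678031
70,0.0127495722226972
71,0.0141278719621395
72,0.0156587641069885
73,0.0173591422555825
74,0.0192477703068428
75,0.0213454895223931
76,0.0236754485126518
77,0.0262633586848258
78,0.029137777971707
79,0.032330425972257
80,0.0358765339815989
81,0.0398152337730421
82,0.044189989422404
83,0.0490490769398638
84,0.0544461170021534
85,0.0604406666638531
86,0.0670988765774073
87,0.0744942209743676
88,0.0827083084633059
89,0.0918317825916596
90,0.101965322109328
91,0.113220751972061
92,0.125722277344713
93,0.139607854221749
94,0.155030711789982
95,0.172161043333024
96,0.191187884336792
97,0.212321198521227
98,0.23579419481786
99,0.261865900861371
100,0.290824021393973
101,0.322988113125494
102,0.358713111084148
103,0.398393245371761
104,0.442466391545353
105,0.491418902632118
106,0.545790976099744
107,0.606182615007276
108,0.673260249118643
109,0.747764089043695
110,0.830516294560693
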