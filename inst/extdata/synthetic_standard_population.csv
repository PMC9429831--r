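"age","weight"
25,0.025088135
26,0.024714621
27,0.024346668
28,0.023984194
29,0.023627116
30,0.023275354
31,0.022928829
32,0.022587463
33,0.02225118
34,0.021919903
35,0.021593558
36,0.021272072
37,0.020955372
38,0.020643387
39,0.020336047
40,0.020033283
41,0.019735026
42,0.01944121
43,0.019151768
44,0.018866635
45,0.018585747
46,0.018309042
47,0.018036456
48,0.017767928
49,0.017503398
50,0.017242806
51,0.016986094
52,0.016733204
53,0.016484079
54,0.016238663
55,0.015996901
56,0.015758738
57,0.015524121
58,0.015292997
59,0.015065314
60,0.014841021
61,0.014620067
62,0.014402402
63,0.014187978
64,0.013976747
65,0.01376866
66,0.013563672
67,0.013361735
68,0.013162805
69,0.012966836
70,0.012773785
71,0.012583608
72,0.012396263
73,0.012211706
74,0.012029898
75,0.011850796
76,0.01167436
77,0.011500552
78,0.011329331
79,0.011160659
80,0.010994499
81,0.010830812
82,0.010669562
83,0.010510713
84,0.010354229
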