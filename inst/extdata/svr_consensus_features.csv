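feature_number,roi_i,roi_j,weight
200,6,3,3.4199
208,14,3,4.0323
302,12,4,0.1837
308,18,4,6.7691
514,35,6,1.9686
515,36,6,3.9004
517,38,6,1.5754
523,44,6,0.417
632,60,7,2.8031
785,30,9,0.5353
871,26,10,7.0751
881,36,10,7.2001
910,65,10,1.5674
955,21,11,1.6761
957,23,11,0.026
961,27,11,4.6158
1037,15,12,11.408
1038,16,12,3.0458
1044,22,12,3.501
1047,25,12,6.4695
1048,26,12,4.8864
1139,30,13,4.3102
1213,18,14,5.4143
1218,23,14,3.4732
1231,36,14,4.6873
1233,38,14,2.9394
1239,44,14,0.6638
1260,65,14,3.6222
1306,26,15,1.8433
1387,23,16,1.2731
1398,34,16,2.0425
1560,31,18,0.7004
1727,37,20,2.9906
1730,40,20,0.8001
1732,42,20,3.3381
1739,49,20,2.0195
1791,22,21,3.8335
1795,26,21,3.2795
1870,23,22,5.1255
1880,33,22,0.8944
1881,34,22,1.3206
1882,35,22,2.0233
1883,36,22,4.7918
1949,25,23,2.8737
1950,26,23,1.0806
1954,30,23,1.6872
1960,36,23,6.069
2006,82,23,2.2798
2016,92,23,4.7532
2110,35,25,3.9079
2113,38,25,2.0904
2176,27,26,0.2893
2182,33,26,3.067
2183,34,26,0.8171
2184,35,26,3.9006
2190,41,26,2.0477
2217,68,26,12.328
2252,30,27,4.8758
2258,36,27,3.5564
2262,40,27,2.4206
2267,45,27,4.0491
2271,49,27,1.7481
2299,77,27,1.608
2301,79,27,9.5243
2302,80,27,3.2888
2304,82,27,2.3834
2308,86,27,2.5869
2311,89,27,1.6131
2313,91,27,4.0015
2314,92,27,3.1354
2315,93,27,1.4905
2317,95,27,1.2658
2340,46,28,2.9832
2343,49,28,0.9104
2344,50,28,1.5884
2374,80,28,2.164
2399,34,29,1.8317
2439,74,29,5.2682
2441,76,29,3.9293
2472,37,30,1.2744
2509,74,30,3.1864
2511,76,30,10.158
2540,36,31,0.0347
2542,38,31,4.5939
2551,47,31,4.293
2561,57,31,2.0379
2562,58,31,0.1465
2570,66,31,0.6321
2573,69,31,3.8353
2606,34,32,1.6084
2617,45,32,5.5595
2618,46,32,6.3606
2620,48,32,5.3524
2806,36,35,5.942
2829,59,35,2.5231
2876,42,36,2.0429
2884,50,36,0.8906
2887,53,36,2.8127
2889,55,36,0.6196
2908,74,36,3.0879
2935,38,37,1.3538
2977,80,37,2.6368
2989,92,37,1.0198
2992,95,37,1.227
3001,42,38,0.0421
3009,50,38,2.5175
3012,53,38,1.0882
3013,54,38,1.5278
3022,63,38,0.5381
3033,74,38,1.6784
3094,74,39,1.1764
3160,80,40,1.114
3172,92,40,0.7809
3181,42,41,7.0436
3255,58,42,3.3164
3256,59,42,3.9536
3268,71,42,1.1748
3274,77,42,0.681
3276,79,42,5.519
3277,80,42,2.2915
3289,92,42,2.2737
3298,44,43,4.8264
3320,66,43,2.3284
3328,74,43,4.3556
3330,76,43,3.8301
3357,47,44,1.4419
3363,53,44,3.9555
3366,56,44,3.59
3367,57,44,8.5639
3368,58,44,0.9669
3372,62,44,6.2692
3376,66,44,2.2942
3377,67,44,4.238
3379,69,44,3.356
3386,76,44,2.344
3521,49,47,1.7159
3537,65,47,1.2226
3542,70,47,2.969
3546,74,47,2.8436
3548,76,47,1.9436
3553,81,47,0.1955
3598,74,48,2.8843
3600,76,48,5.3379
3633,58,49,3.0962
3634,59,49,1.2744
3683,58,50,0.4134
3684,59,50,6.6085
3690,65,50,0.1353
3705,80,50,4.0167
3835,66,53,7.7145
3926,66,55,0.6183
3973,69,56,0.6484
4021,74,57,5.2334
4061,72,58,2.2855
4062,73,58,1.2126
4063,74,58,3.3874
4065,76,58,0.0311
4095,65,59,1.0257
4104,74,59,6.1957
4249,65,63,4.0141
4253,69,63,1.0645
4255,71,63,0.5269
4264,80,63,3.5363
4286,66,64,2.2027
4299,79,64,1.9985
4311,91,64,2.8954
4334,79,65,11.855
4335,80,65,0.2271
4400,78,67,1.0522
4430,76,68,1.6719
4441,87,68,1.6202
4516,72,71,2.2346
4518,74,71,1.3602
4521,77,71,0.1952
4530,86,71,2.9293
4552,80,72,1.2155
4602,77,74,3.939
4609,84,74,3.9741
4651,77,76,0.8857
4683,86,77,0.214
4686,89,77,3.7542
4759,99,80,1.0681
4802,88,83,8.7927
4812,98,83,2.3099
4814,100,83,1.5265
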