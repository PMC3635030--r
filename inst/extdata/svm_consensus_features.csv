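feature_number,weight
632,0.3119
1037,0.4479
1038,0.2472
1047,0.1405
1048,0.203
1231,0.0986
1233,0.1508
1727,0.121
1732,0.2313
1795,0.0542
1950,0.1294
2110,0.1074
2183,0.0652
2301,0.0016
2311,0.1118
2314,0.0027
2315,0.0074
2441,0.3302
2509,0.0548
2511,0.3977
2542,0.1668
2551,0.029
2605,0.2421
2606,0.1719
2618,0.1803
2884,0.0787
2887,0.0787
2908,0.112
2935,0.0752
2989,0.0487
3033,0.1055
3094,0.0269
3256,0.1804
3277,0.0604
3298,0.1927
3328,0.0331
3330,0.1669
3357,0.1524
3367,0.1008
3368,0.0787
3376,0.021
3379,0.0593
3546,0.0535
3548,0.2019
3598,0.0234
3835,0.2415
3926,0.2598
4021,0.2507
4061,0.1886
4063,0.0089
4065,0.1549
4095,0.241
4104,0.0656
4249,0.1736
4299,0.3015
4311,0.2509
4334,0.3287
4430,0.1071
4518,0.1153
4602,0.1964
4683,0.2273
4802,0.379
4812,0.0522
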