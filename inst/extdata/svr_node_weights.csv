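roi_index,roi_name,weight
3,M_mPFC,0.3062
4,L_aPFC_2,3.4764
6,R_aPFC_2,1.7403
7,L_vent_aPFC,1.4016
9,R_vlPFC,0.2676
10,R_ACC,0.8462
11,R_dlPFC_1,3.133
12,R_sup_frontal,14.747
13,R_vPFC,2.1551
14,M_ACC_1,1.7177
15,L_sup_frontal,6.6258
16,M_ACC_2,3.1807
18,L_vPFC,5.7415
20,R_vFC_1,2.5547
21,R_ant_insula,4.3946
22,R_dACC,0.0952
23,L_ant_insula,10.848
25,L_basal_ganglia_1,3.7628
26,M_mFC,2.6519
27,R_frontal_1,4.1057
28,L_vFC_1,1.3242
29,R_dFC_2,3.6829
30,R_dFC_3,0.6411
31,L_dFC,3.3619
32,L_vFC_2,1.4715
33,L_basal_ganglia_2,1.0863
34,R_basal_ganglia_1,0.9506
35,L_vFC_3,1.7332
36,R_pre_SMA,0.6284
37,R_vFC_2,1.6506
38,M_SMA,2.2
39,R_frontal_2,0.5882
40,R_precentral_gyrus_1,0.1372
41,L_thalamus_1,2.4979
42,L_mid_insula_1,2.1402
43,L_precentral_gyrus_1,0.9863
44,L_parietal_1,5.0775
45,R_precentral_gyrus_2,4.8043
46,L_precentral_gyrus_2,4.6719
47,R_precentral_gyrus_3,1.8094
48,L_parietal_2,3.903
49,R_mid_insula_1,2.0883
50,L_mid_insula_2,6.3615
53,R_mid_insula_2,0.071
54,R_temporal_1,0.7639
55,L_mid_insula_3,0.6189
56,L_parietal_3,2.1192
57,L_parietal_4,5.8797
58,R_parietal_1,2.3834
59,L_parietal_5,9.7648
60,L_precentral_gyrus_3,1.4016
62,R_parietal_2,3.1346
63,R_post_insula,0.8258
64,R_basal_ganglia_2,1.3456
65,M_post_cingulate,6.4323
66,R_parietal_3,5.6008
67,L_parietal_6,1.5929
68,L_post_insula,6.1384
69,L_parietal_7,3.8037
70,R_temporal_2,1.4845
71,L_post_parietal_1,1.9759
72,L_temporal_2,2.8678
73,L_temporal_3,0.6063
74,L_precuneus_1,5.8246
76,R_precuneus_1,15.035
77,L_IPL_1,4.7624
78,R_parietal_4,0.5261
79,L_post_cingulate_1,2.9254
80,R_precuneus_2,2.2972
81,R_temporal_3,0.0978
82,R_IPL_1,0.0518
83,L_parietal_8,4.7881
84,L_post_parietal_2,1.987
86,L_IPL_2,2.6511
87,L_angular_gyrus_1,0.8101
88,L_IPL_3,4.3964
89,R_precuneus_3,2.6837
91,L_post_cingulate_2,0.553
92,R_post_cingulate,0.4474
93,L_precuneus_2,0.7453
95,L_post_cingulate_3,1.2464
98,L_angular_gyrus_2,1.1549
99,R_precuneus_4,0.534
100,L_IPS_2,0.7632
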