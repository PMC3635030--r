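roi_index,roi_name,weight
7,L_vent_aPFC,0.1559
12,R_sup_frontal,0.5193
14,M_ACC_1,0.1247
15,L_sup_frontal,0.2239
16,M_ACC_2,0.1236
20,R_vFC_1,0.1761
21,R_ant_insula,0.0271
23,L_ant_insula,0.0647
25,L_basal_ganglia_1,0.0165
26,M_mFC,0.0229
27,R_frontal_1,0.0591
29,R_dFC_2,0.1651
30,R_dFC_3,0.1714
31,L_dFC,0.0979
32,L_vFC_2,0.1169
33,L_basal_ganglia_2,0.1211
34,R_basal_ganglia_1,0.1185
35,L_vFC_3,0.0537
36,R_pre_SMA,0.072
37,R_vFC_2,0.0473
38,M_SMA,0.0232
39,R_frontal_2,0.0135
42,L_mid_insula_1,0.0556
43,L_precentral_gyrus_1,0.1963
44,L_parietal_1,0.3025
46,L_precentral_gyrus_2,0.0901
47,R_precentral_gyrus_3,0.1649
48,L_parietal_2,0.0117
50,L_mid_insula_2,0.0394
53,R_mid_insula_2,0.1601
55,L_mid_insula_3,0.1299
57,L_parietal_4,0.1758
58,R_parietal_1,0.0181
59,L_parietal_5,0.0631
60,L_precentral_gyrus_3,0.1559
63,R_post_insula,0.0868
64,R_basal_ganglia_2,0.2762
65,M_post_cingulate,0.043
66,R_parietal_3,0.2401
68,L_post_insula,0.0536
69,L_parietal_7,0.0296
71,L_post_parietal_1,0.0577
72,L_temporal_2,0.0943
74,L_precuneus_1,0.4059
76,R_precuneus_1,0.5722
77,L_IPL_1,0.2118
79,L_post_cingulate_1,0.0128
80,R_precuneus_2,0.0302
83,L_parietal_8,0.2156
86,L_IPL_2,0.1137
88,L_IPL_3,0.1895
89,R_precuneus_3,0.0559
91,L_post_cingulate_2,0.1255
92,R_post_cingulate,0.023
93,L_precuneus_2,0.0037
98,L_angular_gyrus_2,0.0261
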