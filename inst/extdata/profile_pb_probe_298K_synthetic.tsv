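# free-energy profile: T = 298 K, a = 1 A
# r_A  G_kJ_per_mol
1	-1.802926014
1.661016949	-23.02943734
2.2	-43.84
2.322033898	-42.41679435
2.983050847	-11.26526596
3.644067797	-0.4310665683
4.305084746	0.1287901088
4.966101695	7.142622552
5.627118644	56.08183835
6	76.32
6.288135593	63.49444931
6.949152542	10.36569378
7.610169492	0.2440113811
8.271186441	0.0008282680053
8.93220339	4.053972352e-07
9.593220339	2.861144379e-11
10.25423729	2.911708265e-16
10.91525424	4.272725957e-22
11.57627119	9.040892665e-29
12.23728814	2.758459943e-36
12.89830508	1.21358764e-44
13.55932203	7.6988295e-54
14.22033898	7.042508069e-64
14.88135593	9.289216802e-75
15.54237288	1.766769686e-86
16.20338983	4.845402663e-99
16.86440678	1.916147348e-112
17.52542373	1.092639824e-126
18.18644068	8.984093083e-142
18.84745763	1.065173994e-157
19.50847458	1.821025221e-174
20.16949153	4.48911221e-192
20.83050847	1.595710328e-210
21.49152542	8.178934777e-230
22.15254237	6.044891753e-250
22.81355932	6.442128836e-271
23.47457627	9.899639458e-293
24.13559322	2.193605065e-315
24.79661017	0
25.45762712	0
26.11864407	0
26.77966102	0
27.44067797	0
28.10169492	0
28.76271186	0
29.42372881	0
30.08474576	0
30.74576271	0
31.40677966	0
32.06779661	0
32.72881356	0
33.38983051	0
34.05084746	0
34.71186441	0
35.37288136	0
36.03389831	0
36.69491525	0
37.3559322	0
38.01694915	0
38.6779661	0
39.33898305	0
40	0
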