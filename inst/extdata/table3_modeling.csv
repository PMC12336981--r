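compound_id,S,Tor,MP,NRB,repul,eta,pIC50_obs,pIC50_pred_mlr,resid_mlr,pIC50_pred_mnlr,resid_mnlr,split
1,3.1684,5.3358,1221.15,9,4588.56,0.073775,7.31,7.324,-0.011,7.345,-0.032,train
2,2.5717,5.4927,1161.91,9,3983.94,0.07366,6.76,6.944,-0.180,6.793,-0.028,train
3,3.3203,14.4563,1169.66,9,4127.68,0.073705,6.75,6.668,0.082,6.829,-0.080,test
4,2.8648,9.6019,1177.41,9,4278.85,0.07379,6.60,6.677,-0.073,6.618,-0.014,test
5,2.7726,7.3625,1173.18,10,4108.00,0.073775,6.75,6.683,0.069,6.721,0.031,train
6,2.9858,5.9475,1151.51,11,4317.95,0.07381,6.45,6.430,0.019,6.436,0.012,train
7,2.8589,2.9396,1112.51,8,3916.85,0.073545,7.43,7.370,0.058,7.425,0.004,train
8,3.0643,10.8436,1153.71,8,4206.83,0.073795,6.97,6.877,0.097,6.875,0.100,train
9,3.1563,5.5693,1218.04,8,4538.53,0.07348,7.56,7.500,0.056,7.521,0.035,train
10,3.1966,4.904,1182.3,8,4727.18,0.073045,7.05,7.118,-0.063,7.195,-0.140,train
11,3.2185,6.2351,1176.76,8,4381.84,0.07354,7.32,7.371,-0.056,7.417,-0.102,train
12,3.0551,1.8107,1255.22,8,4373.21,0.07362,7.65,8.170,-0.518,8.148,-0.497,test
13,3.1579,10.1711,1262.97,8,4577.86,0.07402,7.20,7.440,-0.238,7.399,-0.197,train
14,3.2615,5.4632,1269.28,8,4745.28,0.07349,8.00,7.748,0.248,7.780,0.216,train
15,3.3069,1.8001,1197.45,8,4532.35,0.073545,7.69,7.852,-0.159,7.772,-0.080,train
16,3.4701,2.1641,1208.72,9,4693.53,0.073535,7.87,7.641,0.225,7.602,0.265,train
17,3.6827,5.3083,1249.2,10,5007.98,0.073535,7.33,7.274,0.058,7.284,0.048,train
18,3.8117,8.632,1253.43,9,5170.85,0.07361,7.11,7.218,-0.106,7.124,-0.012,train
19,3.4844,2.1634,1269.54,10,4852.38,0.073495,7.64,7.658,-0.014,7.709,-0.065,train
20,3.1592,7.4478,1221.15,9,4625.67,0.074505,7.38,7.231,0.152,7.256,0.127,train
21,2.85,5.3534,1112.51,8,3894.38,0.074075,6.98,7.263,-0.287,7.312,-0.337,test
22,3.5298,6.5685,1178.79,11,4544.13,0.07395,6.87,6.821,0.053,6.827,0.048,train
23,3.238,13.2614,1221.56,9,4502.94,0.074275,6.77,6.829,-0.055,6.811,-0.037,train
24,3.138,8.0742,1218.04,8,4512.91,0.074175,7.86,7.412,0.450,7.359,0.502,test
25,3.208,8.7184,1176.76,8,4336.63,0.07393,7.21,7.250,-0.041,7.260,-0.050,train
26,3.0406,4.2684,1255.22,8,4340.67,0.0742,8.06,8.073,-0.010,8.074,-0.011,train
27,3.1589,12.5753,1262.97,8,4539.71,0.07494,7.54,7.430,0.110,7.494,0.047,train
28,3.2619,7.7031,1269.28,8,4756.57,0.07437,7.79,7.703,0.088,7.672,0.119,train
29,3.298,4.2607,1197.45,8,4524.05,0.07441,7.83,7.793,0.034,7.725,0.102,test
30,3.4583,4.5979,1208.72,9,4691.05,0.074435,7.45,7.584,-0.134,7.552,-0.102,train
31,3.491,4.4959,1269.54,10,4849.24,0.074305,7.44,7.608,-0.167,7.635,-0.194,train
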