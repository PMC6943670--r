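compound_id,ic50_uM,pic50,comfa_pred,comfa_res,comsia_pred,comsia_res,binding_mode,is_test
01,0.333,6.478,6.315,0.163,6.497,-0.019,I,TRUE
02,0.245,6.611,6.490,0.121,6.289,0.322,I,TRUE
03,2.59,5.587,5.658,-0.071,5.831,-0.244,I,FALSE
04,0.121,6.917,6.968,-0.051,6.95,-0.033,I,FALSE
05,0.192,6.717,6.655,0.062,6.632,0.085,I,FALSE
06,0.210,6.678,6.512,0.166,6.299,0.379,I,FALSE
07,0.739,6.131,6.404,-0.273,6.518,-0.387,I,TRUE
08,0.492,6.308,6.322,-0.014,6.275,0.033,I,FALSE
09,0.391,6.408,6.514,-0.106,6.38,0.028,I,FALSE
10,0.197,6.706,6.438,0.268,6.717,-0.011,I,TRUE
11,0.123,6.910,6.886,0.024,7.07,-0.160,I,FALSE
12,10.2,4.991,4.982,0.009,4.94,0.051,I,FALSE
13,4.24,5.373,5.383,-0.010,5.526,-0.153,II,FALSE
14,0.72,6.143,6.107,0.036,6.065,0.078,II,FALSE
15,1.29,5.889,6.188,-0.299,6.121,-0.232,II,FALSE
16,0.92,6.036,6.006,0.030,5.838,0.198,II,FALSE
17,3.57,5.447,5.432,0.015,5.557,-0.110,II,FALSE
18,0.859,6.066,5.884,0.182,5.788,0.278,II,FALSE
19,1.47,5.833,5.88,-0.047,5.945,-0.112,II,FALSE
20,0.364,6.439,6.382,0.057,6.622,-0.183,II,FALSE
21,0.764,6.117,6.078,0.039,6.022,0.095,II,FALSE
22,0.283,6.548,6.566,-0.018,6.361,0.187,II,FALSE
23,2.96,5.529,5.901,-0.372,5.667,-0.138,II,TRUE
24,4.161,5.381,5.429,-0.048,5.388,-0.007,III,TRUE
25,3.315,5.480,5.466,0.014,5.438,0.042,III,FALSE
26,5.185,5.285,5.288,-0.003,5.176,0.109,III,FALSE
27,3.979,5.400,5.534,-0.134,5.553,-0.153,III,TRUE
28,4.666,5.331,5.304,0.027,5.395,-0.0635,III,FALSE
29,0.692,6.160,6.195,-0.035,6.038,0.122,III,FALSE
30,0.816,6.088,6.089,-0.001,6.095,-0.007,III,FALSE
31,1.298,5.887,5.875,0.012,5.837,0.050,III,TRUE
32,0.701,6.154,6.105,0.049,6.271,-0.117,III,FALSE
33,1.93,5.888,5.84,0.0482,5.927,-0.0386,III,FALSE
34,0.891,6.050,6.117,-0.067,6.13,-0.080,III,FALSE
35,16.21,4.790,4.812,-0.022,4.825,-0.035,I,FALSE
36,29.58,4.529,4.513,0.016,4.531,-0.002,I,FALSE
37,10.36,4.985,4.657,0.3282,5.128,-0.1426,I,TRUE
38,36.09,4.443,4.464,-0.021,4.405,0.038,II,FALSE
39,20.14,4.696,4.674,0.022,4.796,-0.100,II,FALSE
40,18.96,4.722,4.747,-0.025,4.769,-0.047,II,FALSE
41,9.03,5.044,5.052,-0.008,5.052,-0.008,II,FALSE
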