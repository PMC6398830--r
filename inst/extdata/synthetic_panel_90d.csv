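date,CO,NO2,O3,SO2,PCNT,PM2.5,temperature,rel_humidity,count
2011-01-01,0.093,11.271,53.44,0.01,5.876,0.01,6.4,82.6,34
2011-01-02,,11.901,65.575,0.01,4.256,2.274,6.3,75.2,28
2011-01-03,0.049,1.177,71.797,0.01,5.709,0.01,5.6,70.3,29
2011-01-04,0.039,0.221,69.888,0.01,3.354,0.01,-0.3,89,43
2011-01-05,0.059,0.01,84.726,0.01,4.269,0.01,5.5,77.2,33
2011-01-06,0.018,4.055,73.441,0.01,3.784,0.01,7.8,87.9,26
2011-01-07,0.029,5.216,85.206,0.01,6.692,0.01,6.5,73.2,31
2011-01-08,0.01,0.406,81.437,0.01,2.427,0.01,3.8,85.6,36
2011-01-09,0.01,0.01,70.738,0.01,6.338,0.01,7,80.5,23
2011-01-10,0.056,3.721,61.475,0.572,7.035,0.01,5.5,82.7,40
2011-01-11,0.058,7.164,61.613,0.232,5.464,0.435,6,82,43
2011-01-12,0.135,2.261,57.213,2.553,7.671,1.231,6.4,77.3,55
2011-01-13,0.179,7.759,51.59,2.006,6.324,0.01,5.3,85.1,58
2011-01-14,0.136,5.658,50.38,1.706,6.072,7.994,8.3,75.8,58
2011-01-15,,18.993,59.265,1.822,9.452,6.075,8,65.8,56
2011-01-16,0.191,14.399,59.091,2.082,7.025,3.266,6.3,72.5,69
2011-01-17,0.241,20.005,54.944,1.658,10.505,4.866,9.2,75.6,55
2011-01-18,0.185,16.292,43.666,2.183,8.907,5.287,3.7,84.8,62
2011-01-19,0.237,20.447,38.352,2.229,10.386,7.718,9.2,72.3,74
2011-01-20,0.204,24.561,49.272,3.081,9.092,3.211,6.1,87.5,80
2011-01-21,0.261,21.763,49.247,2.678,,4.999,8,73.3,74
2011-01-22,0.237,20.461,51.698,3.441,9.395,5.068,11.3,72.9,63
2011-01-23,0.249,31.091,57.326,4.003,10.714,10.68,9.7,74.6,79
2011-01-24,0.237,21.239,45.515,3.784,8.872,4.969,7.3,66.6,68
2011-01-25,0.308,34.963,54.615,2.141,10.92,9.417,12.6,75.9,77
2011-01-26,0.23,37.69,55.756,2.87,11.454,9.882,6.8,80.9,75
2011-01-27,0.244,31.25,49.212,3.062,10.77,10.599,7.6,73.1,96
2011-01-28,0.34,40.3,43.403,2.621,11.151,17.244,11.9,70.1,83
2011-01-29,0.285,26.813,50.404,1.928,11.633,,9.6,76.4,94
2011-01-30,0.205,31.336,43.219,0.966,11.39,10.663,10.1,80.1,81
2011-01-31,0.291,22.671,54.392,1.042,9.698,12.388,8.2,72.8,81
2011-02-01,0.288,23.872,50.93,1.05,11.893,12.373,8.8,76.7,89
2011-02-02,0.218,32.128,45.44,1.368,11.437,11.398,10.9,70.2,112
2011-02-03,0.239,42.757,38.345,1.448,11.566,15.641,11.6,75.3,94
2011-02-04,0.289,36.428,44.656,0.684,9.007,15.489,8.5,80.4,114
2011-02-05,0.256,36.334,41.435,1.14,11.294,13.329,8.5,77,100
2011-02-06,0.285,,39.072,2.175,11.991,22.707,9.8,74.5,105
2011-02-07,0.222,37.762,43.794,1.672,11.926,19.577,10.7,75.7,87
2011-02-08,0.237,26.627,34.252,1.13,11.442,13.246,9.5,74.7,86
2011-02-09,0.258,40.135,47.74,2.202,11.135,11.133,13.3,67.4,103
2011-02-10,0.276,48.456,33.335,2.043,10.919,14.42,8.7,61.6,105
2011-02-11,0.236,38.154,28.494,2.555,13.549,16.375,7.1,72.2,100
2011-02-12,0.255,30.662,42.683,3.716,12.674,17.576,11.3,74.2,107
2011-02-13,0.218,29.582,35.155,1.627,10.733,17.621,7.8,86.2,98
2011-02-14,0.236,25.487,36.226,2.672,14.848,18.112,11.3,74.6,118
2011-02-15,0.156,39.558,42.194,2.888,12.711,13.001,11.6,73.8,99
2011-02-16,0.217,41.147,40.897,2.216,13.432,16.308,8.1,81.1,102
2011-02-17,0.254,44.183,37.349,2.792,14.364,16.708,12,60.3,97
2011-02-18,0.255,49.523,36.524,3.368,15.823,20.016,9.6,79.4,114
2011-02-19,0.246,36.57,37.802,3.009,16.895,17.056,9.7,88.6,124
2011-02-20,0.29,49.573,24.252,1.391,12.248,17.528,9.4,77.2,110
2011-02-21,0.249,53.573,40.519,1.089,13.861,17.539,9,72.3,125
2011-02-22,0.283,45.648,30.334,2.22,13.657,18.376,14.1,64.3,130
2011-02-23,0.293,35.883,27.891,2.85,14.217,19.279,11.1,67.3,123
2011-02-24,0.336,48.478,35.453,3.607,14.225,19.579,9.3,74.2,149
2011-02-25,0.333,45.298,22.927,3.635,15.003,16.638,13,66.3,132
2011-02-26,0.267,47.336,27.732,2.386,13.637,13.461,12,66.2,132
2011-02-27,0.278,49.799,25.595,3.49,14.408,12.029,15.7,81.4,143
2011-02-28,0.255,41.47,23.731,2.426,14.667,19.044,10.5,75.7,140
2011-03-01,0.303,40.923,38.118,1.861,13.522,9.012,15.6,79.1,156
2011-03-02,0.299,43.379,23.27,2.182,13.934,12.439,14.1,81.7,145
2011-03-03,0.289,41.938,28.509,2.277,11.267,10.949,14,74.1,135
2011-03-04,0.245,45.395,31.21,3.161,11.234,13.184,6.3,76.6,132
2011-03-05,0.276,46.527,32.757,1.808,15.686,,12.7,69.2,131
2011-03-06,,45.315,23.294,3.905,12.637,19.259,12.9,68.4,169
2011-03-07,0.302,49.286,35.298,3.158,15.758,17.006,16.1,74.8,163
2011-03-08,0.332,50.092,25.758,2.873,12.628,,13,80.8,153
2011-03-09,0.413,47.229,26.725,2.96,17.003,19.223,13.4,72.4,191
2011-03-10,0.4,58.59,19.325,2.86,15.771,17.287,12.7,71,205
2011-03-11,0.355,65.291,21.842,5.014,15.392,22.035,12.7,88.2,249
2011-03-12,0.367,59.618,22.141,3.955,16.686,22.897,12.6,75.5,233
2011-03-13,0.422,59.312,8.708,2.928,16.204,20.357,9.4,81.6,231
2011-03-14,0.404,48.098,1.651,1.738,16.667,19.746,14.4,61.3,272
2011-03-15,0.353,49.841,8.422,0.627,16.792,16.118,14.4,60.3,228
2011-03-16,0.34,61.467,8.603,1.715,13.969,,14.3,78.6,197
2011-03-17,0.332,51.513,14.695,0.319,14.045,13.565,14.5,66.5,181
2011-03-18,0.216,47.389,14.223,2.334,,2.072,16.7,61.7,179
2011-03-19,0.306,54.138,9.634,0.856,15.725,10.399,12.8,79.4,176
2011-03-20,0.356,48.005,10.139,1.072,15.886,10.918,12.9,76.2,183
2011-03-21,0.312,54.965,11.936,1.736,15.404,9.026,11.9,78.1,190
2011-03-22,0.343,41.77,10.627,1.142,14.443,11.517,15.4,72.6,192
2011-03-23,0.314,50.008,11.241,1.41,16.217,13.768,15.8,70.5,195
2011-03-24,,48.927,10.591,1.445,17.771,12.974,12.9,82.6,183
2011-03-25,0.388,52.712,4.82,2.347,12.86,6.219,12.8,76.9,206
2011-03-26,0.268,45.927,27.589,1.116,16.294,14.078,17.9,74.2,174
2011-03-27,0.345,,23.713,1.582,14.654,9.181,16.1,72.3,149
2011-03-28,0.302,51.629,15.67,1.589,12.618,10.939,12.7,69.4,164
2011-03-29,0.272,54.236,20.713,0.655,14.768,10.617,12.8,69.1,167
2011-03-30,0.285,41.002,16.807,0.01,13.374,2.913,16.6,64.7,154
2011-03-31,0.193,51.533,14.502,1.799,12.976,10.391,13.3,66.4,146
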