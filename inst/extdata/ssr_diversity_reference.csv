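Marker,MAF,Na,Ho,He,PIC,Fst
SSR101,0.611,10,0.322,0.596,0.572,0.460
SSR125,0.610,14,0.386,0.590,0.561,0.346
SSR136,0.380,7,0.531,0.750,0.712,0.292
SSR138,0.335,8,0.723,0.794,0.767,0.089
SSR192,0.454,20,0.617,0.753,0.735,0.181
SSR198,0.599,12,0.490,0.616,0.598,0.204
SSR206,0.365,26,0.677,0.826,0.814,0.181
SSR207,0.527,6,0.336,0.618,0.557,0.455
SSR22,0.429,10,0.560,0.732,0.696,0.235
SSR221,0.490,16,0.693,0.725,0.708,0.045
SSR222,0.209,40,0.601,0.916,0.911,0.344
SSR227,0.233,23,0.461,0.850,0.834,0.458
SSR228,0.498,13,0.501,0.686,0.651,0.269
SSR229,0.474,9,0.546,0.654,0.596,0.164
SSR238,0.413,12,0.467,0.760,0.733,0.386
SSR247,0.346,7,0.579,0.701,0.644,0.174
SSR256,0.177,16,0.732,0.864,0.849,0.153
SSR266,0.415,30,0.356,0.787,0.771,0.547
SSR283,0.388,6,0.556,0.725,0.678,0.234
SSR45,0.456,7,0.414,0.671,0.614,0.383
SSR56,0.495,7,0.513,0.624,0.555,0.177
SSR66,0.283,10,0.551,0.780,0.744,0.293
SSR90,0.452,5,0.586,0.690,0.640,0.151
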