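"age_days","L","M","S"
0,1,0.5,0.035
91,1,0.5856,0.035
182,1,0.651,0.035
273,1,0.702,0.035
364,1,0.7426,0.035
455,1,0.7759,0.035
546,1,0.8038,0.035
637,1,0.8278,0.035
728,1,0.8492,0.035
819,1,0.8685,0.035
910,1,0.8865,0.035
1001,1,0.9034,0.035
1092,1,0.9196,0.035
1183,1,0.9353,0.035
1274,1,0.9507,0.035
1365,1,0.9657,0.035
1456,1,0.9806,0.035
1547,1,0.9953,0.035
1638,1,1.0099,0.035
1729,1,1.0245,0.035
1820,1,1.039,0.035
1911,1,1.0535,0.035
2002,1,1.0679,0.035
2093,1,1.0823,0.035
2184,1,1.0967,0.035
2275,1,1.1111,0.035
2366,1,1.1255,0.035
2457,1,1.1399,0.035
2548,1,1.1543,0.035
2639,1,1.1687,0.035
2730,1,1.183,0.035
2821,1,1.1974,0.035
2912,1,1.2118,0.035
3003,1,1.2262,0.035
3094,1,1.2406,0.035
3185,1,1.2549,0.035
3276,1,1.2693,0.035
3367,1,1.2837,0.035
3458,1,1.2981,0.035
3549,1,1.3124,0.035
3640,1,1.3268,0.035
3731,1,1.3412,0.035
3822,1,1.3557,0.035
3913,1,1.3702,0.035
4004,1,1.3849,0.035
4095,1,1.3998,0.035
4186,1,1.4152,0.035
4277,1,1.4312,0.035
4368,1,1.4482,0.035
4459,1,1.4663,0.035
4550,1,1.4859,0.035
4641,1,1.507,0.035
4732,1,1.5296,0.035
4823,1,1.5533,0.035
4914,1,1.5777,0.035
5005,1,1.602,0.035
5096,1,1.6256,0.035
5187,1,1.648,0.035
5278,1,1.6686,0.035
5369,1,1.6871,0.035
5460,1,1.7036,0.035
5551,1,1.718,0.035
5642,1,1.7304,0.035
5733,1,1.7409,0.035
5824,1,1.7498,0.035
5915,1,1.757,0.035
6006,1,1.7628,0.035
6097,1,1.7673,0.035
6188,1,1.7708,0.035
6279,1,1.7734,0.035
6370,1,1.7753,0.035
6461,1,1.7767,0.035
6552,1,1.7777,0.035
6643,1,1.7784,0.035
6734,1,1.7789,0.035
6825,1,1.7793,0.035
6916,1,1.7795,0.035
7007,1,1.7797,0.035
7098,1,1.7798,0.035
7189,1,1.7799,0.035
7280,1,1.78,0.035
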