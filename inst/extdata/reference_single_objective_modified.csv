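sample,precision,sensitivity,f_measure,accuracy,specificity,time_s
1,0.8934,0.9421,0.8751,93.26,0.6059,8.04
2,0.8773,0.9512,0.9424,94.32,0.6132,7.23
3,0.8609,0.9359,0.8961,93.43,0.5943,7.20
4,0.9023,0.9645,0.9118,95.12,0.6202,6.99
5,0.9112,0.9574,0.8143,94.64,0.6089,7.42
6,0.8996,0.9465,0.8875,93.62,0.5885,8.65
7,0.9247,0.9224,0.8465,95.12,0.6209,7.85
8,0.9145,0.9471,0.9053,93.46,0.6011,6.84
9,0.9319,0.9565,0.9162,95.73,0.6289,7.65
10,0.9272,0.9623,0.9253,94.33,0.6376,8.56
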