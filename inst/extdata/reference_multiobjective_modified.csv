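sample,precision,sensitivity,f_measure,accuracy,specificity,time_s
1,0.9154,0.9998,0.8987,96.43,0.6059,6.24
2,0.9212,0.9854,0.9874,97.43,0.6132,5.45
3,0.8976,0.9995,0.9543,95.33,0.5943,6.32
4,0.9123,0.9775,0.9872,96.78,0.6202,4.65
5,0.9222,0.9987,0.8872,95.87,0.6089,5.9
6,0.908,0.9734,0.8973,97.87,0.5885,5.89
7,0.9432,0.9934,0.8972,96.04,0.6209,4.89
8,0.9231,0.9991,0.9965,96.87,0.6011,5.98
9,0.9342,0.9886,0.9763,97.77,0.6289,6.76
10,0.9298,0.9787,0.9832,96.87,0.6376,6.99
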