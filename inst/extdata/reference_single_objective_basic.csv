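sample,precision,sensitivity,f_measure,accuracy,specificity,time_s
1,0.8848,0.8915,0.8271,92.34,0.5721,3.81
2,0.8612,0.8761,0.9124,91.59,0.5832,3.49
3,0.8459,0.8929,0.8626,92.63,0.5674,3.9
4,0.8139,0.8817,0.8921,93.22,0.5874,4.21
5,0.8712,0.8787,0.7731,91.84,0.5743,3.67
6,0.8956,0.8965,0.8251,92.92,0.5575,3.99
7,0.8777,0.8682,0.7827,93.31,0.5434,4.34
8,0.845,0.8775,0.8565,91.54,0.5598,3.38
9,0.8719,0.8843,0.8736,94.02,0.5774,4.46
10,0.8064,0.9023,0.8906,92.77,0.5823,3.97
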