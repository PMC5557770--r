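subject_id,auc,sensitivity,specificity,threshold
1,0.69,0.56,0.79,0.53
2,0.66,0.90,0.41,0.26
3,0.90,0.92,0.76,0.22
4,0.79,1.00,0.79,0.20
5,0.69,1.00,0.41,0.23
6,0.87,0.88,0.75,0.49
11,0.90,1.00,0.67,0.72
12,0.75,0.64,0.83,0.19
16,0.80,0.74,0.81,0.59
17,0.51,0.73,0.37,0.23
18,0.75,0.80,0.75,0.57
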