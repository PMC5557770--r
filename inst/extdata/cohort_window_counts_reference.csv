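subject_id,gait_windows,prefog_windows,paired_conditions
1,204,16,7
2,111,10,4
3,21,12,3
4,184,1,1
5,162,4,4
6,236,33,9
11,12,4,1
12,275,11,3
16,407,19,6
17,435,22,8
18,81,5,4
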