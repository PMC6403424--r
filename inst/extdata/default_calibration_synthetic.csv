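"time_days","mean_length_nm","mean_length_se","cd_signal"
0,12,1,1
0.5,295.3422,1,0.928889
1,343.3906,1,0.868642
1.5,392.66,1,0.81913
2,419.6026,1,0.777671
3,441.0892,1,0.710544
4,443.8146,1,0.656029
5,439.061,1,0.608785
6,431.0873,1,0.566318
7,421.6959,1,0.527421
8,411.6948,1,0.491464
9,401.4586,1,0.458077
10,391.1662,1,0.427011
11,380.9065,1,0.398074
12,370.7258,1,0.371107
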