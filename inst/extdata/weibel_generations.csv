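generation,position_cm,area_cm2,alveoli_fraction
0,0,0.10559,0
1,11.9797,0.337223,0
2,16.7317,0.712869,0
3,18.6285,1.06328,0
4,19.3872,1.27982,0
5,20.6551,1.82369,0
6,21.7233,2.60445,0
7,22.6217,3.727,0
8,23.3804,5.35472,0
9,24.0194,7.72209,0
10,24.5585,11.1956,0
11,25.0177,16.403,0
12,25.407,24.3002,0
13,25.7365,36.4715,0
14,26.006,54.797,0
15,26.2356,83.9968,0
16,26.4353,133.584,0
17,26.6,217,0.005
18,26.7,386,0.01
19,26.8,683,0.02
20,26.9,1157,0.04
21,27,2329,0.1
22,27.1,4252,0.2764
23,27.2,8534,0.5486
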