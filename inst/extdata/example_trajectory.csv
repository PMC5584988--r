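time_s,x_mm,z_mm
0,0.043,0.375
1,-0.109,0.181
2,0.028,0.165
3,0.107,0.287
4,-0.055,0.233
5,-0.017,0.347
6,0.24,0.445
7,0.177,0.328
8,-0.022,0.499
9,0.109,0.186
10,0.127,0.578
11,-0.034,0.348
12,0.075,0.266
13,0.17,0.457
14,0.041,0.453
15,-0.161,0.306
16,0.072,0.191
17,0.023,0.379
18,-0.057,0.205
19,0.121,0.445
20,-0.095,0.331
21,-0.254,0.329
22,-0.161,0.438
23,0.027,0.392
24,0.16,0.213
25,-0.046,-1.503
26,0.053,-1.121
27,0.2,-1.37
28,-0.059,-1.487
29,0.083,-1.08
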