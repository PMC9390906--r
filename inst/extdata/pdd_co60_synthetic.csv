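depth_cm,pdd_percent
0.5,100
1,98.2
2,94.8
3,90.6
4,86.4
5,82.3
6,78.2
7,74.2
8,70.3
10,62.9
12,56.1
15,46.9
20,34.7
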