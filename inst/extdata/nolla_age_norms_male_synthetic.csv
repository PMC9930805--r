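age,score
3,28.696
3.2,29.928
3.4,31.141
3.6,32.336
3.8,33.512
4,34.67
4.2,35.809
4.4,36.929
4.6,38.031
4.8,39.114
5,40.179
5.2,41.225
5.4,42.253
5.6,43.262
5.8,44.253
6,45.224
6.2,46.178
6.4,47.113
6.6,48.029
6.8,48.927
7,49.806
7.2,50.666
7.4,51.509
7.6,52.332
7.8,53.137
8,53.923
8.2,54.691
8.4,55.44
8.6,56.171
8.8,56.883
9,57.577
9.2,58.252
9.4,58.908
9.6,59.546
9.8,60.165
10,60.766
10.2,61.348
10.4,61.912
10.6,62.457
10.8,62.984
11,63.491
11.2,63.981
11.4,64.452
11.6,64.904
11.8,65.338
12,65.753
12.2,66.149
12.4,66.528
12.6,66.887
12.8,67.228
13,67.55
13.2,67.854
13.4,68.139
13.6,68.406
13.8,68.654
14,68.884
14.2,69.095
14.4,69.287
14.6,69.461
14.8,69.616
15,69.753
15.2,69.871
15.4,69.971
15.6,70.052
15.8,70.115
16,70.158
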