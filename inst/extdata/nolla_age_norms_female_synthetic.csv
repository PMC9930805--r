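age,score
3,26.692
3.2,28.185
3.4,29.652
3.6,31.093
3.8,32.507
4,33.895
4.2,35.256
4.4,36.591
4.6,37.899
4.8,39.181
5,40.436
5.2,41.665
5.4,42.867
5.6,44.043
5.8,45.192
6,46.315
6.2,47.412
6.4,48.482
6.6,49.525
6.8,50.542
7,51.532
7.2,52.496
7.4,53.434
7.6,54.345
7.8,55.23
8,56.088
8.2,56.919
8.4,57.724
8.6,58.503
8.8,59.255
9,59.981
9.2,60.68
9.4,61.353
9.6,61.999
9.8,62.619
10,63.212
10.2,63.779
10.4,64.319
10.6,64.833
10.8,65.32
11,65.781
11.2,66.216
11.4,66.624
11.6,67.005
11.8,67.36
12,67.688
12.2,67.99
12.4,68.266
12.6,68.515
12.8,68.738
13,68.934
13.2,69.103
13.4,69.246
13.6,69.363
13.8,69.453
14,69.517
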