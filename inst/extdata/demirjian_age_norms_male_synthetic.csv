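age,score
3.5,32.744
3.6,34.902
3.7,37.746
3.8,39.168
3.9,40.434
4,40.944
4.1,41.443
4.2,41.942
4.3,42.696
4.4,43.51
4.5,44.625
4.6,46.71
4.7,48.299
4.8,50.298
4.9,52.562
5,54.443
5.1,56.092
5.2,57.574
5.3,58.358
5.4,58.962
5.5,59.717
5.6,59.946
5.7,60.24
5.8,60.439
5.9,60.893
6,61.549
6.1,62.099
6.2,63.209
6.3,64.133
6.4,65.398
6.5,66.502
6.6,67.644
6.7,68.749
6.8,69.824
6.9,70.632
7,71.136
7.1,71.654
7.2,72.037
7.3,72.29
7.4,72.491
7.5,72.723
7.6,72.994
7.7,73.426
7.8,73.513
7.9,74.41
8,75.296
8.1,75.902
8.2,76.618
8.3,77.867
8.4,79.393
8.5,80.207
8.6,81.847
8.7,82.65
8.8,83.702
8.9,84.378
9,85.173
9.1,85.855
9.2,86.07
9.3,86.704
9.4,86.798
9.5,87.142
9.6,87.228
9.7,87.525
9.8,87.539
9.9,87.898
10,88.025
10.1,88.267
10.2,88.597
10.3,89.103
10.4,89.373
10.5,90.022
10.6,90.495
10.7,91.299
10.8,91.892
10.9,92.653
11,93.453
11.1,94.049
11.2,94.624
11.3,95.205
11.4,95.921
11.5,96.383
11.6,96.974
11.7,97.34
11.8,97.988
11.9,98.249
12,98.598
12.1,98.862
12.2,98.996
12.3,99.347
12.4,99.42
12.5,99.533
12.6,99.632
12.7,99.701
12.8,99.778
12.9,99.832
13,99.847
13.1,99.883
13.2,99.891
13.3,99.932
13.5,99.95
13.7,99.986
14,99.991
14.2,99.998
14.4,100
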