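age,score
3.5,23.041
3.6,26.435
3.7,29.378
3.8,32.98
3.9,35.599
4,38.272
4.1,39.313
4.2,40.165
4.3,40.835
4.4,41.428
4.5,42.276
4.6,43.437
4.7,45.463
4.8,47.453
4.9,49.81
5,52.16
5.1,54.661
5.2,56.389
5.3,57.68
5.4,58.602
5.5,59.178
5.6,59.461
5.7,59.763
5.8,60.335
5.9,61.058
6,61.989
6.1,63.231
6.2,64.721
6.3,66.225
6.4,67.787
6.5,69.146
6.6,70.393
6.7,71.268
6.8,72.094
6.9,72.552
7,72.979
7.1,73.182
7.2,73.362
7.3,73.931
7.4,74.535
7.5,75.138
7.6,75.772
7.7,76.768
7.8,78.344
7.9,79.776
8,81.006
8.1,82.662
8.2,83.881
8.3,85.074
8.4,86.019
8.5,86.915
8.6,87.506
8.7,87.938
8.8,88.154
8.9,88.502
9,88.712
9.1,88.974
9.2,89.154
9.3,89.404
9.4,89.54
9.5,90.04
9.6,90.555
9.7,90.966
9.8,91.545
9.9,92.002
10,92.757
10.1,93.512
10.2,94.171
10.3,95.1
10.4,95.712
10.5,96.377
10.6,96.769
10.7,97.377
10.8,97.798
10.9,98.268
11,98.569
11.1,98.898
11.2,99.092
11.3,99.28
11.4,99.494
11.5,99.604
11.6,99.656
11.7,99.692
11.8,99.718
11.9,99.823
12,99.857
12.1,99.902
12.2,99.918
12.3,99.952
12.4,99.957
12.6,99.974
12.7,99.983
12.9,99.984
13,99.986
13.1,99.99
13.2,100
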