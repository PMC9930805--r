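tooth,stage,score
37,0,0
37,A,2.1
37,B,3.5
37,C,5.9
37,D,10.1
37,E,12.5
37,F,13.2
37,G,13.6
37,H,15.4
36,0,0
36,A,0
36,B,0
36,C,0
36,D,8
36,E,9.6
36,F,12.3
36,G,17
36,H,19.3
35,0,0
35,A,1.7
35,B,3.1
35,C,5.4
35,D,9.7
35,E,12
35,F,12.8
35,G,13.2
35,H,14.4
34,0,0
34,A,0
34,B,0
34,C,3.4
34,D,7
34,E,11
34,F,12.3
34,G,12.7
34,H,13.5
33,0,0
33,A,0
33,B,0
33,C,0
33,D,3.5
33,E,7.9
33,F,10
33,G,11
33,H,11.9
32,0,0
32,A,0
32,B,0
32,C,0
32,D,3.2
32,E,5.2
32,F,7.8
32,G,11.7
32,H,13.7
31,0,0
31,A,0
31,B,0
31,C,0
31,D,0
31,E,1.9
31,F,4.1
31,G,8.2
31,H,11.8
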