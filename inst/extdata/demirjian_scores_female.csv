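tooth,stage,score
37,0,0
37,A,2.7
37,B,3.9
37,C,6.9
37,D,11.1
37,E,13.5
37,F,14.2
37,G,14.5
37,H,15.6
36,0,0
36,A,0
36,B,0
36,C,0
36,D,4.5
36,E,6.2
36,F,9
36,G,14
36,H,16.2
35,0,0
35,A,1.8
35,B,3.4
35,C,6.5
35,D,10.6
35,E,12.7
35,F,13.5
35,G,13.8
35,H,14.6
34,0,0
34,A,0
34,B,0
34,C,3.7
34,D,7.5
34,E,11.8
34,F,13.1
34,G,13.4
34,H,14.1
33,0,0
33,A,0
33,B,0
33,C,0
33,D,3.8
33,E,7.3
33,F,10.3
33,G,11.6
33,H,12.4
32,0,0
32,A,0
32,B,0
32,C,0
32,D,3.2
32,E,5.6
32,F,8
32,G,12.2
32,H,14.2
31,0,0
31,A,0
31,B,0
31,C,0
31,D,0
31,E,2.4
31,F,5.1
31,G,9.3
31,H,12.9
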