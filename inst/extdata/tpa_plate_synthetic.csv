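concentration,well,count
0,1,0
0,2,0
0,3,0
0,4,0
0,5,0
0,6,1
10,1,0
10,2,1
10,3,2
10,4,2
10,5,2
10,6,6
20,1,0
20,2,1
20,3,2
20,4,3
20,5,3
20,6,4
50,1,0
50,2,1
50,3,3
50,4,3
50,5,4
50,6,5
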