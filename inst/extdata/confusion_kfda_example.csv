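"",W,S,J,GD,GU,SC,R,L
W,531,2,3,10,8,5,2,3
S,3,461,2,3,4,2,6,2
J,2,1,450,5,6,5,2,2
GD,10,2,4,456,3,9,4,1
GU,12,5,8,2,439,1,5,0
SC,8,3,3,12,1,446,9,5
R,5,9,3,2,6,12,480,5
L,1,1,1,0,1,1,1,353
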