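{"width":12,"depth":10,"elevation":[8,8,7,6,6,6,5,5,5,4,4,4,8,7,6,6,5,5,5,5,4,4,3,3,8,7,6,6,5,5,5,5,4,3,3,2,8,7,7,6,5,5,5,4,4,3,3,2,9,8,7,6,6,5,5,5,5,4,4,4,9,8,7,7,6,5,5,5,5,5,5,5,9,9,8,8,7,6,5,5,5,5,5,5,9,9,9,8,6,5,5,5,4,5,5,4,9,9,9,8,6,4,4,4,3,3,3,3,9,9,9,8,6,4,3,3,2,2,2,1],"obstructed":[0,0,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0]}
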