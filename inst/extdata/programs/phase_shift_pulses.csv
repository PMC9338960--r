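target,start,duration,red,green,blue,repeats,interval,message,buzzer
A01,0,3,0,0,255,12,300,,
B01,0,3,0,0,255,12,300,,
C01,1800,3,0,0,255,6,300,,
D01,1800,3,0,0,255,6,300,,
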