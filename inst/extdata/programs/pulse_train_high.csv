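target,start,duration,red,green,blue,repeats,interval,message,buzzer
A01,0,10,0,0,255,42,120,,
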