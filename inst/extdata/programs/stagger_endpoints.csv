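target,start,duration,red,green,blue,repeats,interval,message,buzzer
A01,1320,10,0,0,255,1,,,
A02,1200,10,0,0,255,1,,,
A03,1080,10,0,0,255,1,,,
A04,960,10,0,0,255,1,,,
A05,840,10,0,0,255,1,,,
A06,720,10,0,0,255,1,,,
A07,600,10,0,0,255,1,,,
A08,480,10,0,0,255,1,,,
A09,360,10,0,0,255,1,,,
A10,240,10,0,0,255,1,,,
A11,120,10,0,0,255,1,,,
A12,0,10,0,0,255,1,,,
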