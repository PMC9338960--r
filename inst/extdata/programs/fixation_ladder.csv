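target,start,duration,red,green,blue,repeats,interval,message,buzzer
B01,660,2,0,0,255,1,,,
B02,600,2,0,0,255,1,,,
B03,540,2,0,0,255,1,,,
B04,480,2,0,0,255,1,,,
B05,420,2,0,0,255,1,,,
B06,360,2,0,0,255,1,,,
B07,300,2,0,0,255,1,,,
B08,240,2,0,0,255,1,,,
B09,180,2,0,0,255,1,,,
B10,120,2,0,0,255,1,,,
B11,60,2,0,0,255,1,,,
B12,0,2,0,0,255,1,,,
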