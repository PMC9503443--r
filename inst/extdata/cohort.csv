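id,gender,age,weight,height,initial_hr,final_hr,duration
P1,M,22,64.2,172,93,191,570
P2,M,33,66.9,177,70,180,960
P3,F,19,64.2,177,87,191,545
P4,M,36,83.2,182,91,191,900
P5,F,24,66.6,170,97,184,560
P6,F,29,47,157,114,193,480
P7,M,33,83,186,101,180,960
P8,M,22,90.7,195,101,201,720
P9,M,24,87.3,194,115,188,660
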