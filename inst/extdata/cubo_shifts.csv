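class,center_ppm,tolerance_ppm
PC,0.00,0.10
LPC,0.30,0.10
SM,-0.45,0.10
PI,0.60,0.10
PE,0.95,0.10
PG,1.55,0.10
PS,1.25,0.10
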