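quantity,value
D,63.7
A,-4.4362
T,0.274
sd_water_H,1.0
sa_water_O,1.0
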