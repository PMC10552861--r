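object,mean_pct,sd_pct
Circular Plate (Small),-1.31,4.82
Circular Plate (Medium),0.96,4.66
Circular Plate (Large),5.28,4.39
Square Plate (Small),2.71,4.38
Square Plate (Medium),2.40,4.73
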