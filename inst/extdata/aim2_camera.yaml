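# Factory parameters of the wearable camera (distortion-corrected frame).
fc_mm: 2.4
sensor_w_mm: 3.67
sensor_h_mm: 2.74
img_w: 3378
img_h: 2347
ccx: 1689.0
ccy: 1173.5
scx: 920.4359673024523
scy: 856.5693430656934
kc: 0.0
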