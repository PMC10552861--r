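object,height_cm,pitch_deg,dtof_mm,predicted_cm,original_cm,error_pct
Circular Plate (Small),20,42,460,16.95,18,-5.84
Circular Plate (Small),20,56,425,16.56,18,-8.00
Circular Plate (Small),20,64,390,19.07,18,5.94
Circular Plate (Small),35,38,740,17.13,18,-4.86
Circular Plate (Small),35,55,580,17.37,18,-3.48
Circular Plate (Small),35,72,550,18.92,18,5.11
Circular Plate (Small),50,41,870,17.61,18,-2.15
Circular Plate (Small),50,53,755,18.23,18,1.28
Circular Plate (Small),50,67,680,18.04,18,0.24
Circular Plate (Medium),20,42,460,20.59,22,-6.42
Circular Plate (Medium),20,56,425,21.14,22,-3.93
Circular Plate (Medium),20,64,390,23.36,22,6.17
Circular Plate (Medium),35,38,740,22.51,22,2.30
Circular Plate (Medium),35,55,580,21.47,22,-2.40
Circular Plate (Medium),35,72,550,23.73,22,7.84
Circular Plate (Medium),50,41,870,22.01,22,0.04
Circular Plate (Medium),50,53,755,22.79,22,3.60
Circular Plate (Medium),50,67,680,22.33,22,1.50
Circular Plate (Large),20,42,460,25.71,26,-1.12
Circular Plate (Large),20,56,425,25.91,26,-0.33
Circular Plate (Large),20,64,390,28.41,26,9.27
Circular Plate (Large),35,38,740,27.81,26,6.95
Circular Plate (Large),35,55,580,26.99,26,3.81
Circular Plate (Large),35,72,550,29.39,26,13.05
Circular Plate (Large),50,41,870,27.21,26,4.65
Circular Plate (Large),50,53,755,27.53,26,5.89
Circular Plate (Large),50,67,680,27.39,26,5.34
Square Plate (Small),20,42,460,17.31,18,-3.83
Square Plate (Small),20,56,425,17.86,18,-0.80
Square Plate (Small),20,64,390,19.37,18,7.62
Square Plate (Small),35,38,740,18.33,18,1.81
Square Plate (Small),35,55,580,18.34,18,1.91
Square Plate (Small),35,72,550,19.88,18,10.46
Square Plate (Small),50,41,870,18.92,18,5.10
Square Plate (Small),50,53,755,18.03,18,0.18
Square Plate (Small),50,67,680,18.35,18,1.93
Square Plate (Medium),20,42,460,21.98,23,-4.43
Square Plate (Medium),20,56,425,22.14,23,-3.72
Square Plate (Medium),20,64,390,24.83,23,7.96
Square Plate (Medium),35,38,740,23.93,23,4.06
Square Plate (Medium),35,55,580,23.09,23,0.38
Square Plate (Medium),35,72,550,25.18,23,9.48
Square Plate (Medium),50,41,870,24.07,23,4.64
Square Plate (Medium),50,53,755,23.21,23,0.90
Square Plate (Medium),50,67,680,23.54,23,2.35
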