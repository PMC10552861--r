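object,height_cm,pitch_deg,dtof_mm,predicted_cm,original_cm,error_pct
Circular Bowl (Small),20,42,460,1.96,3,-34.60
Circular Bowl (Small),20,56,425,3.04,3,1.30
Circular Bowl (Small),20,64,390,4.44,3,48.00
Circular Bowl (Small),35,38,740,1.69,3,-43.77
Circular Bowl (Small),35,55,580,2.13,3,-29.10
Circular Bowl (Small),35,72,550,4.31,3,43.60
Circular Bowl (Small),50,41,870,1.65,3,-45.00
Circular Bowl (Small),50,53,755,2.26,3,-24.83
Circular Bowl (Small),50,67,680,3.53,3,17.77
Circular Bowl (Medium),20,42,460,6.13,7,-12.41
Circular Bowl (Medium),20,56,425,7.83,7,11.81
Circular Bowl (Medium),20,64,390,1.01,7,-85.60
Circular Bowl (Medium),35,38,740,5.70,7,-18.64
Circular Bowl (Medium),35,55,580,5.74,7,-17.98
Circular Bowl (Medium),35,72,550,10.77,7,53.86
Circular Bowl (Medium),50,41,870,3.69,7,-47.29
Circular Bowl (Medium),50,53,755,5.31,7,-24.17
Circular Bowl (Medium),50,67,680,8.95,7,27.89
Circular Bowl (Large),20,42,460,5.17,6,-13.87
Circular Bowl (Large),20,56,425,7.95,6,32.43
Circular Bowl (Large),20,64,390,10.32,6,72.05
Circular Bowl (Large),35,38,740,4.43,6,-26.17
Circular Bowl (Large),35,55,580,5.57,6,-7.18
Circular Bowl (Large),35,72,550,9.85,6,64.13
Circular Bowl (Large),50,41,870,4.61,6,-23.22
Circular Bowl (Large),50,53,755,5.57,6,-7.11
Circular Bowl (Large),50,67,680,6.84,6,13.95
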