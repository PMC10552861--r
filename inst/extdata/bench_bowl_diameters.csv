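object,height_cm,pitch_deg,dtof_mm,predicted_cm,original_cm,error_pct
Circular Bowl (Small),20,42,460,6.90,7,-1.43
Circular Bowl (Small),20,56,425,6.97,7,-0.43
Circular Bowl (Small),20,64,390,7.59,7,8.43
Circular Bowl (Small),35,38,740,7.02,7,0.29
Circular Bowl (Small),35,55,580,7.55,7,7.86
Circular Bowl (Small),35,72,550,7.79,7,11.29
Circular Bowl (Small),50,41,870,7.35,7,5.00
Circular Bowl (Small),50,53,755,7.18,7,2.57
Circular Bowl (Small),50,67,680,7.27,7,3.86
Circular Bowl (Medium),20,42,460,10.28,11,-6.55
Circular Bowl (Medium),20,56,425,10.26,11,-6.73
Circular Bowl (Medium),20,64,390,11.94,11,8.55
Circular Bowl (Medium),35,38,740,10.26,11,-6.73
Circular Bowl (Medium),35,55,580,11.64,11,5.82
Circular Bowl (Medium),35,72,550,12.66,11,15.09
Circular Bowl (Medium),50,41,870,11.53,11,4.82
Circular Bowl (Medium),50,53,755,11.49,11,4.45
Circular Bowl (Medium),50,67,680,11.44,11,4.00
Circular Bowl (Large),20,42,460,14.62,15,-2.53
Circular Bowl (Large),20,56,425,14.41,15,-3.93
Circular Bowl (Large),20,64,390,17.44,15,16.27
Circular Bowl (Large),35,38,740,15.11,15,0.73
Circular Bowl (Large),35,55,580,16.92,15,12.80
Circular Bowl (Large),35,72,550,17.55,15,17.00
Circular Bowl (Large),50,41,870,15.97,15,6.47
Circular Bowl (Large),50,53,755,16.00,15,6.67
Circular Bowl (Large),50,67,680,16.49,15,9.93
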