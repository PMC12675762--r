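phase,source,plane,L1-L2,L1-L3,L1-L4,L2-L3,L2-L4,L3-L4,rmse_deg
preoperative,Manual,coronal,1.44,2.90,1.19,3.80,2.09,3.93,0.00
preoperative,Manual,sagittal,1.98,4.59,1.21,6.29,1.25,1.08,0.00
preoperative,System,coronal,1.75,2.34,0.45,2.68,0.11,5.71,1.25
preoperative,System,sagittal,1.86,5.37,0.90,5.34,0.93,1.87,0.63
preoperative,M1,coronal,2.18,3.44,0.47,3.35,0.38,5.86,1.17
preoperative,M1,sagittal,9.46,12.65,0.95,5.03,8.57,9.18,6.35
preoperative,M2,coronal,1.97,2.99,0.51,3.11,0.32,5.68,1.11
preoperative,M2,sagittal,10.75,14.07,0.94,5.15,9.45,10.19,7.28
preoperative,M3,coronal,2.21,3.79,0.45,3.68,0.34,6.22,1.31
preoperative,M3,sagittal,13.56,12.66,1.07,4.95,12.80,9.31,8.19
preoperative,M4,coronal,1.99,3.04,0.48,3.05,0.31,5.56,1.10
preoperative,M4,sagittal,10.86,14.22,0.96,5.24,10.24,9.40,7.33
preoperative,M5,coronal,1.58,2.80,0.50,2.69,1.44,4.79,0.71
preoperative,M5,sagittal,4.24,7.89,0.97,5.54,4.61,3.02,2.30
preoperative,M6,coronal,1.73,2.47,0.49,2.53,1.52,5.03,0.81
preoperative,M6,sagittal,3.97,7.42,1.04,4.81,3.52,3.47,2.04
preoperative,M7,coronal,1.60,2.72,0.47,2.74,1.43,4.82,0.70
preoperative,M7,sagittal,4.86,8.34,1.01,5.73,4.24,3.65,2.53
preoperative,M8,coronal,1.76,2.44,0.46,2.65,1.55,4.89,0.75
preoperative,M8,sagittal,3.59,7.25,1.03,4.64,3.44,3.39,1.94
postoperative,Manual,coronal,0.83,3.43,0.17,2.60,1.01,0.17,0.00
postoperative,Manual,sagittal,4.00,17.25,19.66,17.60,20.00,2.41,0.00
postoperative,System,coronal,24.55,22.92,21.25,10.71,9.04,45.35,24.35
postoperative,System,sagittal,25.80,15.61,27.37,2.19,13.94,12.20,12.30
postoperative,M1,coronal,0.24,0.79,0.03,3.21,2.40,4.02,2.02
postoperative,M1,sagittal,9.27,12.40,19.93,1.29,8.81,3.13,8.59
postoperative,M2,coronal,0.69,0.98,0.06,3.85,2.81,4.27,2.15
postoperative,M2,sagittal,8.98,13.34,19.88,2.51,9.05,2.14,8.04
postoperative,M3,coronal,0.23,0.79,0.05,3.21,2.38,4.04,2.02
postoperative,M3,sagittal,9.57,12.54,19.90,1.12,8.48,2.97,8.74
postoperative,M4,coronal,0.68,0.98,0.05,3.84,2.81,4.26,2.14
postoperative,M4,sagittal,8.58,13.20,19.89,2.77,9.46,2.29,7.84
postoperative,M5,coronal,1.19,3.38,0.05,0.04,3.29,0.21,1.41
postoperative,M5,sagittal,5.76,11.13,19.89,3.51,12.27,4.41,7.10
postoperative,M6,coronal,1.62,3.19,0.06,0.58,3.71,0.01,1.42
postoperative,M6,sagittal,5.52,12.14,19.91,4.76,12.53,3.43,6.46
postoperative,M7,coronal,1.17,3.36,0.04,0.04,3.29,0.20,1.41
postoperative,M7,sagittal,6.04,11.27,19.90,3.37,12.00,4.28,7.19
postoperative,M8,coronal,1.63,3.19,0.04,0.58,3.73,0.01,1.43
postoperative,M8,sagittal,5.07,11.94,19.91,5.01,12.98,3.61,6.31
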