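source,target
Ptp2_S258,Hog1_T174
Ptp2_S258,Hog1_T174_Y176
Ptc1,Hog1_T174
Ptc1,Hog1_T174_Y176
Ssk2_S53_S57,Pbs2_S68
Ssk2_S53_S57,Pbs2_S248
Ssk2_S53_S57,Pbs2_S269
Ste11_Ste50_complex,Pbs2_S269
Sho1,Ste20_T511
Cdc42,Ste20_T511
Ste4,Ste20_T511
Nbp2_S196,Ptc1
Fus3_T180_Y182,Dig2_T225
Ypk1_S644_S653,Gpd1_S24_S27
Gpd1_S24_S27,Hog1_T174_Y176
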