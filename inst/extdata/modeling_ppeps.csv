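ppep_id,protein,sites
Ste20_T511,Ste20,T511
Ste20_S195,Ste20,S195
Ste20_T573,Ste20,T573
Ste20_T203_T207,Ste20,T203_T207
Ste20_S418,Ste20,S418
Ste20_S192,Ste20,S192
Ste20_T546,Ste20,T546
Hog1_T174,Hog1,T174
Hog1_T174_Y176,Hog1,T174_Y176
Pbs2_S68,Pbs2,S68
Pbs2_S248,Pbs2,S248
Pbs2_S269,Pbs2,S269
Ssk1_S110,Ssk1,S110
Ssk1_S673,Ssk1,S673
Dig1_S272,Dig1,S272
Dig1_S330,Dig1,S330
Fus3_T180_Y182,Fus3,T180_Y182
Sln1_S1076,Sln1,S1076
Ste11_S323,Ste11,S323
Ste50_S202,Ste50,S202
Ptp2_S258,Ptp2,S258
Gpd1_S24_S27,Gpd1,S24_S27
Hot1_S153,Hot1,S153
Ste12_S400,Ste12,S400
Dig2_T225,Dig2,T225
Far1_S114,Far1,S114
Ypk1_S644_S653,Ypk1,S644_S653
Bit61_S139_S144,Bit61,S139_S144
Nbp2_S196,Nbp2,S196
Ssk2_S53_S57,Ssk2,S53_S57
Sko1_S126,Sko1,S126
Rck2_S519,Rck2,S519
Msn4_S316,Msn4,S316
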