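source,target
Sho1,Ste20_T573
Ssk2_S53_S57,Pbs2_S68
Ste11_Ste50_complex,Pbs2_S269
Ptp2_S258,Hog1_T174_Y176
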