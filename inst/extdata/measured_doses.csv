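phantom,protocol,organ,dose_mGy,sigma_mGy
adult,DoubleSPR,lung,0.19,0.01
adult,STD,lung,14.30,0.70
adult,LD,lung,3.88,0.19
adult,ULD,lung,1.24,0.06
adult,AutoMA,lung,11.90,0.60
adult,AutoSmartMA,lung,9.29,0.46
pediatric_5yr,CfC-120,thyroid,6.84,0.25
pediatric_5yr,CfC-80,thyroid,5.93,0.31
pediatric_5yr,CfC-120-TCM,thyroid,4.05,0.25
pediatric_5yr,CfC-80-TCM,thyroid,3.02,0.13
pediatric_5yr,CfC-120,lung,6.12,0.27
pediatric_5yr,CfC-80,lung,4.58,0.22
pediatric_5yr,CfC-120-TCM,lung,5.13,0.23
pediatric_5yr,CfC-80-TCM,lung,3.66,0.16
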