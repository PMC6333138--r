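label,d_exp_mGy,d_exp_sigma,d_sim_mGy
STD/lung,14.30,0.72,13.24
LD/lung,3.88,0.19,3.64
ULD/lung,1.24,0.06,1.21
AutoMA/lung,11.90,0.60,14.11
AutoSmartMA/lung,9.29,0.46,11.23
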