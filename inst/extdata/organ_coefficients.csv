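organ,tube_voltage,f_organ,f_sigma,source
lung,120,1.50,0.06,synthetic-free literature coefficient (Huda-style CTDIvol-to-organ-dose factor for a 70 kg adult chest)
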