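organ,tube_voltage,mu_en_rho_organ,mu_en_rho_air
lung,120,0.0365,0.0339
thyroid,120,0.0402,0.0339
lung,80,0.0557,0.0521
thyroid,80,0.0610,0.0521
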