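region,theta_ratio,theta_bbp,sensitivity,specificity
North Atlantic subpolar gyre,0.0063,0.0033,74,99
Patagonian shelf,0.0069,0.0035,72,100
Indian sector of the Southern Ocean,0.0078,0.0019,60,98
Atlantic sector of the Southern Ocean,0.0064,0.0021,73,94
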