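MATTF1
MATTF2
MATTF3
MATTF4
ENDO01
GRDDN01
HK0200
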