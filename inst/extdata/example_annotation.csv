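z,y,x,identity
46,54,46,polar
46,39,46,polar
46,46,72,border
59,46,59,border
59,46,33,border
46,46,20,border
33,46,33,border
33,46,59,border
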