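dose,n,dead
50,60,21
150,60,38
450,60,52
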