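,A,B
A,0,50
B,50,0
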