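>ERE ERE
A [ 0 0 0 0 20 5 5 5 0 0 20 0 0 ]
C [ 0 0 0 20 0 5 5 5 0 0 0 20 20 ]
G [ 20 20 0 0 0 5 5 5 0 20 0 0 0 ]
T [ 0 0 20 0 0 5 5 5 20 0 0 0 0 ]
>HSE HSE
A [ 5 0 20 20 5 5 0 0 0 5 5 0 20 20 5 ]
C [ 5 0 0 0 5 5 0 0 20 5 5 0 0 0 5 ]
G [ 5 20 0 0 5 5 0 0 0 5 5 20 0 0 5 ]
T [ 5 0 0 0 5 5 20 20 0 5 5 0 0 0 5 ]
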