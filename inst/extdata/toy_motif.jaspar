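>TOY1 synthetic toy motif
A [ 85  5  2  5 80 ]
C [  5  5 90  5  5 ]
G [  5 85  3  5 10 ]
T [  5  5  5 85  5 ]
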