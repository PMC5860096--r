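ID TOY2
BF synthetic toy motif
XX
P0      A      C      G      T
01     80      6      8      6      A
02      6      8     80      6      G
03      6     80      6      8      C
04     80      6      8      6      A
05      6      6      8     80      T
XX
//
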