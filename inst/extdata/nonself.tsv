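A	0.96999999999999997	0.01000000000000000	0.01000000000000000	0.01000000000000000	0.01000000000000000
C	0.01000000000000000	0.96999999999999997	0.01000000000000000	0.01000000000000000	0.01000000000000000
G	0.01000000000000000	0.01000000000000000	0.96999999999999997	0.96999999999999997	0.01000000000000000
T	0.01000000000000000	0.01000000000000000	0.01000000000000000	0.01000000000000000	0.96999999999999997
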