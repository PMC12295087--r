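>SYN0001 XBP1s_synthetic
A [  2 18  2 18  1  2  2  2 ]
C [  2  2  2  2  1 18  2  2 ]
G [  2  2 18  2  1  2 18  2 ]
T [ 18  2  2  2 21  2  2 18 ]
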