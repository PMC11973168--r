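MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF CTCF_SYNTH synthetic CTCF-like 19-column matrix (not MA0139.1)
letter-probability matrix: alength= 4 w= 19 nsites= 100 E= 0
0.050000  0.050000  0.050000  0.850000
0.050000  0.050000  0.850000  0.050000
0.050000  0.050000  0.850000  0.050000
0.050000  0.850000  0.050000  0.050000
0.050000  0.850000  0.050000  0.050000
0.850000  0.050000  0.050000  0.050000
0.050000  0.850000  0.050000  0.050000
0.050000  0.850000  0.050000  0.050000
0.850000  0.050000  0.050000  0.050000
0.050000  0.050000  0.850000  0.050000
0.050000  0.050000  0.850000  0.050000
0.050000  0.050000  0.850000  0.050000
0.050000  0.050000  0.850000  0.050000
0.050000  0.050000  0.850000  0.050000
0.050000  0.850000  0.050000  0.050000
0.050000  0.050000  0.850000  0.050000
0.050000  0.850000  0.050000  0.050000
0.050000  0.050000  0.050000  0.850000
0.850000  0.050000  0.050000  0.050000
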