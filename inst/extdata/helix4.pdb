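REMARK   4-residue right-handed alpha-helical Calpha stub (hand-written)
ATOM      1  CA  ALA A   1       2.300   0.000   0.000  1.00  0.00           C
ATOM      2  CA  ALA A   2      -0.399   2.265   1.500  1.00  0.00           C
ATOM      3  CA  ALA A   3      -2.161  -0.787   3.000  1.00  0.00           C
ATOM      4  CA  ALA A   4       1.150  -1.992   4.500  1.00  0.00           C
END
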