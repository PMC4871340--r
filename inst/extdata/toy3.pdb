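ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C
ATOM      3  HA  ALA A   1       1.400   1.000   0.000  1.00  0.00           H
ATOM      4  C   ALA A   1       2.100   1.200   0.000  1.00  0.00           C
ATOM      5  N   GLY A   2       3.400   1.200   0.100  1.00  0.00           N
ATOM      6  CA  GLY A   2       4.500   2.000   0.300  1.00  0.00           C
ATOM      7  H   GLY A   2       3.500   0.300   0.200  1.00  0.00           H
ATOM      8  C   GLY A   2       5.800   1.400   0.100  1.00  0.00           C
ATOM      9  N   SER A   3       6.900   2.200   0.400  1.00  0.00           N
ATOM     10  CA  SER A   3       8.100   1.500   0.600  1.00  0.00           C
END
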