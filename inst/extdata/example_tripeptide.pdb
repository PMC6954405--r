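REMARK synthetic example: idealized ALA-GLY-SER tripeptide (all-atom)
ATOM      1  N   ALA A   1      -0.900   0.800   0.000  1.00  0.00
ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00
ATOM      3  C   ALA A   1       1.200   0.600   0.000  1.00  0.00
ATOM      4  O   ALA A   1       1.200   1.800   0.000  1.00  0.00
ATOM      5  CB  ALA A   1       0.000  -1.000   1.200  1.00  0.00
ATOM      6  N   GLY A   2       2.900   0.800   0.000  1.00  0.00
ATOM      7  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00
ATOM      8  C   GLY A   2       5.000   0.600   0.000  1.00  0.00
ATOM      9  O   GLY A   2       5.000   1.800   0.000  1.00  0.00
ATOM     10  N   SER A   3       6.700   0.800   0.000  1.00  0.00
ATOM     11  CA  SER A   3       7.600   0.000   0.000  1.00  0.00
ATOM     12  C   SER A   3       8.800   0.600   0.000  1.00  0.00
ATOM     13  O   SER A   3       8.800   1.800   0.000  1.00  0.00
ATOM     14  CB  SER A   3       7.600  -1.000   1.200  1.00  0.00
ATOM     15  OG  SER A   3       7.600  -2.000   2.200  1.00  0.00
END
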