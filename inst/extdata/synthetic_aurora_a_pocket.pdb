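REMARK   synthetic Aurora-A-like pocket fixture (not a deposited structure)
ATOM      1  N   LEU A 210      -5.500   0.000  -1.000  1.00  0.00           N
ATOM      2  CA  LEU A 210      -4.500   0.000  -1.000  1.00  0.00           C
ATOM      3  C   LEU A 210      -3.500   0.500  -1.000  1.00  0.00           C
ATOM      4  O   LEU A 210      -3.500   1.700  -1.200  1.00  0.00           O
ATOM      5  CD1 LEU A 210      -4.500  -2.000   0.500  1.00  0.00           C
ATOM      6  N   GLU A 211      -2.700   1.100  -0.900  1.00  0.00           N
ATOM      7  CA  GLU A 211      -2.100   0.000  -1.300  1.00  0.00           C
ATOM      8  C   GLU A 211      -0.600   0.000  -1.100  1.00  0.00           C
ATOM      9  O   GLU A 211       0.000   0.000   0.000  1.00  0.00           O
ATOM     10  N   ALA A 273       8.000  -7.600   0.000  1.00  0.00           N
ATOM     11  CA  ALA A 273       9.000  -7.000   0.000  1.00  0.00           C
ATOM     12  C   ALA A 273      10.000  -7.700  -0.200  1.00  0.00           C
ATOM     13  O   ALA A 273      10.000  -8.900  -0.400  1.00  0.00           O
ATOM     14  CB  ALA A 273       9.000  -6.000   0.700  1.00  0.00           C
ATOM     15  N   LYS A 162      12.500   4.000  -1.500  1.00  0.00           N
ATOM     16  CA  LYS A 162      13.000   3.000  -1.000  1.00  0.00           C
ATOM     17  C   LYS A 162      14.000   3.500  -1.000  1.00  0.00           C
ATOM     18  O   LYS A 162      14.000   4.700  -1.200  1.00  0.00           O
ATOM     19  NZ  LYS A 162      12.000   0.000   0.000  1.00  0.00           N
END
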