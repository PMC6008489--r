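REMARK   synthetic MPS1-like hinge site fixture (not a deposited structure)
ATOM      1  N   MET A 602      -5.500   0.000  -1.000  1.00  0.00           N
ATOM      2  CA  MET A 602      -4.500   0.000  -1.000  1.00  0.00           C
ATOM      3  C   MET A 602      -3.500   0.500  -1.000  1.00  0.00           C
ATOM      4  O   MET A 602      -3.500   1.700  -1.200  1.00  0.00           O
ATOM      5  SD  MET A 602      -4.500  -2.000   0.500  1.00  0.00           S
ATOM      6  N   GLU A 603      -2.700   1.100  -0.900  1.00  0.00           N
ATOM      7  CA  GLU A 603      -2.100   0.000  -1.300  1.00  0.00           C
ATOM      8  C   GLU A 603      -0.600   0.000  -1.100  1.00  0.00           C
ATOM      9  O   GLU A 603       0.000   0.000   0.000  1.00  0.00           O
ATOM     10  N   CYS A 604       1.500  -1.000  -1.000  1.00  0.00           N
ATOM     11  CA  CYS A 604       2.500  -1.000  -1.000  1.00  0.00           C
ATOM     12  C   CYS A 604       3.500  -1.000  -1.000  1.00  0.00           C
ATOM     13  O   CYS A 604       3.500  -2.200  -1.200  1.00  0.00           O
ATOM     14  SG  CYS A 604       2.500  -1.000  -2.500  1.00  0.00           S
ATOM     15  N   GLY A 605       6.000   0.000   0.000  1.00  0.00           N
ATOM     16  CA  GLY A 605       7.000   0.500  -0.500  1.00  0.00           C
ATOM     17  C   GLY A 605       8.000   0.000  -1.000  1.00  0.00           C
ATOM     18  O   GLY A 605       8.000  -1.200  -1.200  1.00  0.00           O
ATOM     19  N   LYS A 553      12.500   4.000  -1.500  1.00  0.00           N
ATOM     20  CA  LYS A 553      13.000   3.000  -1.000  1.00  0.00           C
ATOM     21  C   LYS A 553      14.000   3.500  -1.000  1.00  0.00           C
ATOM     22  O   LYS A 553      14.000   4.700  -1.200  1.00  0.00           O
ATOM     23  CE  LYS A 553      12.000   1.300  -0.600  1.00  0.00           C
ATOM     24  NZ  LYS A 553      12.000   0.000   0.000  1.00  0.00           N
ATOM     25  N   VAL A 539       8.000   7.000   0.800  1.00  0.00           N
ATOM     26  CA  VAL A 539       9.000   6.200   0.800  1.00  0.00           C
ATOM     27  C   VAL A 539      10.000   6.800   0.500  1.00  0.00           C
ATOM     28  O   VAL A 539      10.000   8.000   0.300  1.00  0.00           O
ATOM     29  CB  VAL A 539       9.000   5.200   1.500  1.00  0.00           C
ATOM     30  CG1 VAL A 539       9.000   4.000   2.000  1.00  0.00           C
ATOM     31  N   ILE A 663       8.000  -7.600   0.000  1.00  0.00           N
ATOM     32  CA  ILE A 663       9.000  -7.000   0.000  1.00  0.00           C
ATOM     33  C   ILE A 663      10.000  -7.700  -0.200  1.00  0.00           C
ATOM     34  O   ILE A 663      10.000  -8.900  -0.400  1.00  0.00           O
ATOM     35  CB  ILE A 663       9.000  -6.000   0.700  1.00  0.00           C
ATOM     36  CG1 ILE A 663       9.000  -5.000   1.300  1.00  0.00           C
ATOM     37  CD1 ILE A 663       9.000  -4.000   2.000  1.00  0.00           C
HETATM   38  N1  LIG A   1       0.000   0.000   2.800  1.00  0.00           N
HETATM   39  C2  LIG A   1       1.300   0.200   3.100  1.00  0.00           C
HETATM   40  C3  LIG A   1       2.600   0.400   3.400  1.00  0.00           C
HETATM   41  C4  LIG A   1       3.900   0.300   3.300  1.00  0.00           C
HETATM   42  C7  LIG A   1       5.000   0.200   3.400  1.00  0.00           C
HETATM   43  O1  LIG A   1       6.000   0.000   2.700  1.00  0.00           O
HETATM   44  C8  LIG A   1       7.500   1.500   4.000  1.00  0.00           C
HETATM   45  C10 LIG A   1       9.500   1.000   4.200  1.00  0.00           C
HETATM   46  C9  LIG A   1      10.800   0.500   3.500  1.00  0.00           C
HETATM   47  N2  LIG A   1      12.000   0.000   2.600  1.00  0.00           N
HETATM   48  C5  LIG A   1       9.000   4.000   5.800  1.00  0.00           C
HETATM   49  C6  LIG A   1       9.000  -4.000   5.600  1.00  0.00           C
END
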