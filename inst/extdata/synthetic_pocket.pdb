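REMARK   1 SYNTHETIC test pocket generated for voxattrib demos
REMARK   1 pseudo-residue shell around the origin; not a real protein
ATOM      1 N    SER A   1       6.500   0.000   0.800  1.00  0.00           N
ATOM      2 CA   SER A   1       7.700   0.000   0.000  1.00  0.00           C
ATOM      3 C    SER A   1       8.300   1.000   0.000  1.00  0.00           C
ATOM      4 O    SER A   1       8.700   2.000   0.000  1.00  0.00           O
ATOM      5 OG   SER A   1       5.500   0.800   0.000  1.00  0.00           O
ATOM      6 N    ASP A   2      -6.500   0.000   0.800  1.00  0.00           N
ATOM      7 CA   ASP A   2      -7.700   0.000   0.000  1.00  0.00           C
ATOM      8 C    ASP A   2      -8.300   1.000   0.000  1.00  0.00           C
ATOM      9 O    ASP A   2      -8.700   2.000   0.000  1.00  0.00           O
ATOM     10 CG   ASP A   2      -7.100   0.500   0.000  1.00  0.00           C
ATOM     11 OD1  ASP A   2      -7.900   1.200   0.000  1.00  0.00           O
ATOM     12 OD2  ASP A   2      -7.900  -0.600   0.500  1.00  0.00           O
ATOM     13 N    LYS A   3       0.000   6.500   0.800  1.00  0.00           N
ATOM     14 CA   LYS A   3       0.000   7.700   0.000  1.00  0.00           C
ATOM     15 C    LYS A   3       0.000   9.300   0.000  1.00  0.00           C
ATOM     16 O    LYS A   3       0.000  10.700   0.000  1.00  0.00           O
ATOM     17 NZ   LYS A   3       0.400   5.300   0.300  1.00  0.00           N
ATOM     18 N    PHE A   4       0.000  -6.500   0.800  1.00  0.00           N
ATOM     19 CA   PHE A   4       0.000  -7.700   0.000  1.00  0.00           C
ATOM     20 C    PHE A   4       0.000  -7.300   0.000  1.00  0.00           C
ATOM     21 O    PHE A   4       0.000  -6.700   0.000  1.00  0.00           O
ATOM     22 CG   PHE A   4       1.400  -6.200   0.000  1.00  0.00           C
ATOM     23 CD1  PHE A   4       0.700  -6.200   1.212  1.00  0.00           C
ATOM     24 CD2  PHE A   4      -0.700  -6.200   1.212  1.00  0.00           C
ATOM     25 CE1  PHE A   4      -1.400  -6.200   0.000  1.00  0.00           C
ATOM     26 CE2  PHE A   4      -0.700  -6.200  -1.212  1.00  0.00           C
ATOM     27 CZ   PHE A   4       0.700  -6.200  -1.212  1.00  0.00           C
ATOM     28 N    GLY A   5       0.000   0.000   7.300  1.00  0.00           N
ATOM     29 CA   GLY A   5       0.000   0.000   7.700  1.00  0.00           C
ATOM     30 C    GLY A   5       0.000   1.000   8.300  1.00  0.00           C
ATOM     31 O    GLY A   5       0.000   2.000   8.700  1.00  0.00           O
ATOM     32 N    THR A   6       0.000   0.000  -5.700  1.00  0.00           N
ATOM     33 CA   THR A   6       0.000   0.000  -7.700  1.00  0.00           C
ATOM     34 C    THR A   6       0.000   1.000  -8.300  1.00  0.00           C
ATOM     35 O    THR A   6       0.000   2.000  -8.700  1.00  0.00           O
ATOM     36 CG2  THR A   6      -0.800   0.000  -7.300  1.00  0.00           C
HETATM   37 ZN    ZN A   7       0.000   0.000   7.800  1.00  0.00          ZN
HETATM   38 O    HOH A   8       9.500   9.500   9.500  1.00  0.00           O
END
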