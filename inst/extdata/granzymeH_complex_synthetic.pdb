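HEADER    SYNTHETIC PROTEASE-PEPTIDE COMPLEX (TEST FIXTURE)
REMARK    synthetic CA-only stand-in for a protease bound to a 9-mer substrate
ATOM      1  CA  ALA A   1      -0.399   2.265   1.500  1.00  0.00           C
ATOM      2  CA  ALA A   2      -2.161  -0.787   3.000  1.00  0.00           C
ATOM      3  CA  ALA A   3       1.150  -1.992   4.500  1.00  0.00           C
ATOM      4  CA  ALA A   4       1.762   1.478   6.000  1.00  0.00           C
ATOM      5  CA  ALA A   5      -1.762   1.478   7.500  1.00  0.00           C
ATOM      6  CA  ALA A   6      -1.150  -1.992   9.000  1.00  0.00           C
ATOM      7  CA  ALA A   7       2.161  -0.787  10.500  1.00  0.00           C
ATOM      8  CA  ALA A   8       0.399   2.265  12.000  1.00  0.00           C
ATOM      9  CA  ALA A   9      -2.300   0.000  13.500  1.00  0.00           C
ATOM     10  CA  ALA A  10       0.399  -2.265  15.000  1.00  0.00           C
ATOM     11  CA  ALA A  11       2.161   0.787  16.500  1.00  0.00           C
ATOM     12  CA  ALA A  12      -1.150   1.992  18.000  1.00  0.00           C
ATOM     13  CA  ALA A  13      -1.762  -1.478  19.500  1.00  0.00           C
ATOM     14  CA  ALA A  14       1.762  -1.478  21.000  1.00  0.00           C
ATOM     15  CA  ALA A  15       1.150   1.992  22.500  1.00  0.00           C
ATOM     16  CA  ALA A  16      -2.161   0.787  24.000  1.00  0.00           C
ATOM     17  CA  ALA A  17      -0.399  -2.265  25.500  1.00  0.00           C
ATOM     18  CA  ALA A  18       2.300  -0.000  27.000  1.00  0.00           C
ATOM     19  CA  ALA A  19      -0.399   2.265  28.500  1.00  0.00           C
ATOM     20  CA  ALA A  20      -2.161  -0.787  30.000  1.00  0.00           C
ATOM     21  CA  ALA A  21       1.150  -1.992  31.500  1.00  0.00           C
ATOM     22  CA  ALA A  22       1.762   1.478  33.000  1.00  0.00           C
ATOM     23  CA  ALA A  23      -1.762   1.478  34.500  1.00  0.00           C
ATOM     24  CA  ALA A  24      -1.150  -1.992  36.000  1.00  0.00           C
ATOM     25  CA  ALA A  25       2.161  -0.787  37.500  1.00  0.00           C
ATOM     26  CA  ALA A  26       0.399   2.265  39.000  1.00  0.00           C
ATOM     27  CA  ALA A  27      -2.300   0.000  40.500  1.00  0.00           C
ATOM     28  CA  ALA A  28       0.399  -2.265  42.000  1.00  0.00           C
ATOM     29  CA  ALA A  29       2.161   0.787  43.500  1.00  0.00           C
ATOM     30  CA  ALA A  30      -1.150   1.992  45.000  1.00  0.00           C
TER
ATOM     31  CA  PRO B   1       8.000   0.500   3.800  1.00  0.00           C
ATOM     32  CA  THR B   2       8.000   1.000   7.600  1.00  0.00           C
ATOM     33  CA  SER B   3       8.000   1.500  11.400  1.00  0.00           C
ATOM     34  CA  TYR B   4       8.000   2.000  15.200  1.00  0.00           C
ATOM     35  CA  ALA B   5       8.000   2.500  19.000  1.00  0.00           C
ATOM     36  CA  GLY B   6       8.000   3.000  22.800  1.00  0.00           C
ATOM     37  CA  ASP B   7       8.000   3.500  26.600  1.00  0.00           C
ATOM     38  CA  ASP B   8       8.000   4.000  30.400  1.00  0.00           C
ATOM     39  CA  SER B   9       8.000   4.500  34.200  1.00  0.00           C
TER
END
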