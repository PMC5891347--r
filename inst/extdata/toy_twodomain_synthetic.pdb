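ATOM      1  CA  ALA A   1      -3.800  -2.850  -0.950  1.00  0.00           C
ATOM      2  CA  ALA A   2       0.000  -2.850  -0.950  1.00  0.00           C
ATOM      3  CA  ALA A   3       3.800  -2.850  -0.950  1.00  0.00           C
ATOM      4  CA  ALA A   4      -3.800   0.950  -0.950  1.00  0.00           C
ATOM      5  CA  ALA A   5       0.000   0.950  -0.950  1.00  0.00           C
ATOM      6  CA  ALA A   6       3.800   0.950  -0.950  1.00  0.00           C
ATOM      7  CA  ALA A   7      -3.800   4.750  -0.950  1.00  0.00           C
ATOM      8  CA  ALA A   8       0.000   4.750  -0.950  1.00  0.00           C
ATOM      9  CA  ALA A   9       3.800   4.750  -0.950  1.00  0.00           C
ATOM     10  CA  ALA A  10      -3.800  -2.850   2.850  1.00  0.00           C
ATOM     11  CA  ALA A  11       0.000  -2.850   2.850  1.00  0.00           C
ATOM     12  CA  ALA A  12       3.800  -2.850   2.850  1.00  0.00           C
ATOM     13  CA  ALA A  13      12.230  -3.280   1.530  1.00  0.00           C
ATOM     14  CA  ALA A  14      20.661  -3.710   0.210  1.00  0.00           C
ATOM     15  CA  ALA A  15      29.091  -4.140  -1.110  1.00  0.00           C
ATOM     16  CA  ALA A  16      37.521  -4.570  -2.430  1.00  0.00           C
ATOM     17  CA  ALA A  17      45.952  -5.000  -3.750  1.00  0.00           C
ATOM     18  CA  ALA A  18      43.252  -2.735  -2.250  1.00  0.00           C
ATOM     19  CA  LYS A  19      41.490  -5.787  -0.750  1.00  0.00           C
ATOM     20  NZ  LYS A  19      41.490  -2.287  -0.750  1.00  0.00           N
ATOM     21  CA  ALA A  20      44.802  -6.992   0.750  1.00  0.00           C
ATOM     22  CA  ALA A  21      45.414  -3.522   2.250  1.00  0.00           C
ATOM     23  CA  LYS A  22      41.890  -3.522   3.750  1.00  0.00           C
ATOM     24  NZ  LYS A  22      41.890  -0.022   3.750  1.00  0.00           N
ATOM     25  CA  ALA A  23      45.952   5.000   3.750  1.00  0.00           C
ATOM     26  CA  ALA A  24      43.252   2.735   2.250  1.00  0.00           C
ATOM     27  CA  ALA A  25      41.490   5.787   0.750  1.00  0.00           C
ATOM     28  CA  ALA A  26      44.802   6.992  -0.750  1.00  0.00           C
ATOM     29  CA  ALA A  27      45.414   3.522  -2.250  1.00  0.00           C
ATOM     30  CA  ALA A  28      41.890   3.522  -3.750  1.00  0.00           C
END
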