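HEADER    SYNTHETIC LASSO FIXTURE
REMARK    synthetic geometric construction, not a real protein
SSBOND   1 CYS A    5    CYS A   26
ATOM      1  CA  GLY A   1      28.351  -2.163   0.000  1.00  0.00
ATOM      2  CA  GLY A   2      24.589  -1.622   0.000  1.00  0.00
ATOM      3  CA  GLY A   3      20.828  -1.082   0.000  1.00  0.00
ATOM      4  CA  GLY A   4      17.067  -0.541   0.000  1.00  0.00
ATOM      5  CA  CYS A   5      13.305   0.000   0.000  1.00  0.00
ATOM      6  CA  GLY A   6      12.766   3.749   0.000  1.00  0.00
ATOM      7  CA  GLY A   7      11.193   7.193   0.000  1.00  0.00
ATOM      8  CA  GLY A   8       8.713  10.056   0.000  1.00  0.00
ATOM      9  CA  GLY A   9       5.527  12.103   0.000  1.00  0.00
ATOM     10  CA  GLY A  10       1.894  13.170   0.000  1.00  0.00
ATOM     11  CA  GLY A  11      -1.894  13.170   0.000  1.00  0.00
ATOM     12  CA  GLY A  12      -5.527  12.103   0.000  1.00  0.00
ATOM     13  CA  GLY A  13      -8.713  10.056   0.000  1.00  0.00
ATOM     14  CA  GLY A  14     -11.193   7.193   0.000  1.00  0.00
ATOM     15  CA  GLY A  15     -12.766   3.749   0.000  1.00  0.00
ATOM     16  CA  GLY A  16     -13.305   0.000   0.000  1.00  0.00
ATOM     17  CA  GLY A  17     -12.766  -3.749   0.000  1.00  0.00
ATOM     18  CA  GLY A  18     -11.193  -7.193   0.000  1.00  0.00
ATOM     19  CA  GLY A  19      -8.713 -10.056   0.000  1.00  0.00
ATOM     20  CA  GLY A  20      -5.527 -12.103   0.000  1.00  0.00
ATOM     21  CA  GLY A  21      -1.894 -13.170   0.000  1.00  0.00
ATOM     22  CA  GLY A  22       1.894 -13.170   0.000  1.00  0.00
ATOM     23  CA  GLY A  23       5.527 -12.103   0.000  1.00  0.00
ATOM     24  CA  GLY A  24       8.713 -10.056   0.000  1.00  0.00
ATOM     25  CA  GLY A  25      11.193  -7.193   0.000  1.00  0.00
ATOM     26  CA  CYS A  26      12.766  -3.749   0.000  1.00  0.00
ATOM     27  CA  GLY A  27      16.493  -3.749   0.745  1.00  0.00
ATOM     28  CA  GLY A  28      20.286  -3.749   0.946  1.00  0.00
ATOM     29  CA  GLY A  29      24.082  -3.749   1.136  1.00  0.00
ATOM     30  CA  GLY A  30      27.877  -3.749   1.326  1.00  0.00
ATOM     31  CA  GLY A  31      31.672  -3.749   1.515  1.00  0.00
ATOM     32  CA  GLY A  32      35.468  -3.749   1.705  1.00  0.00
ATOM     33  CA  GLY A  33      39.263  -3.749   1.895  1.00  0.00
ATOM     34  CA  GLY A  34      43.058  -3.749   2.085  1.00  0.00
ATOM     35  CA  GLY A  35      46.853  -3.749   2.274  1.00  0.00
ATOM     36  CA  GLY A  36      50.649  -3.749   2.464  1.00  0.00
END
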