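HEADER    SYNTHETIC LASSO FIXTURE
REMARK    synthetic geometric construction, not a real protein
SSBOND   1 CYS A    5    CYS A   30
ATOM      1  CA  GLY A   1      30.814  -1.832   0.000  1.00  0.00
ATOM      2  CA  GLY A   2      27.041  -1.374   0.000  1.00  0.00
ATOM      3  CA  GLY A   3      23.269  -0.916   0.000  1.00  0.00
ATOM      4  CA  GLY A   4      19.497  -0.458   0.000  1.00  0.00
ATOM      5  CA  CYS A   5      15.725   0.000   0.000  1.00  0.00
ATOM      6  CA  GLY A   6      15.268   3.763   0.000  1.00  0.00
ATOM      7  CA  GLY A   7      13.923   7.308   0.000  1.00  0.00
ATOM      8  CA  GLY A   8      11.770  10.427   0.000  1.00  0.00
ATOM      9  CA  GLY A   9       8.933  12.941   0.000  1.00  0.00
ATOM     10  CA  GLY A  10       5.576  14.703   0.000  1.00  0.00
ATOM     11  CA  GLY A  11       1.895  15.610   0.000  1.00  0.00
ATOM     12  CA  GLY A  12      -1.895  15.610   0.000  1.00  0.00
ATOM     13  CA  GLY A  13      -5.576  14.703   0.000  1.00  0.00
ATOM     14  CA  GLY A  14      -8.933  12.941   0.000  1.00  0.00
ATOM     15  CA  GLY A  15     -11.770  10.427   0.000  1.00  0.00
ATOM     16  CA  GLY A  16     -13.923   7.308   0.000  1.00  0.00
ATOM     17  CA  GLY A  17     -15.268   3.763   0.000  1.00  0.00
ATOM     18  CA  GLY A  18     -15.725  -0.000   0.000  1.00  0.00
ATOM     19  CA  GLY A  19     -15.268  -3.763   0.000  1.00  0.00
ATOM     20  CA  GLY A  20     -13.923  -7.308   0.000  1.00  0.00
ATOM     21  CA  GLY A  21     -11.770 -10.427   0.000  1.00  0.00
ATOM     22  CA  GLY A  22      -8.933 -12.941   0.000  1.00  0.00
ATOM     23  CA  GLY A  23      -5.576 -14.703   0.000  1.00  0.00
ATOM     24  CA  GLY A  24      -1.895 -15.610   0.000  1.00  0.00
ATOM     25  CA  GLY A  25       1.895 -15.610   0.000  1.00  0.00
ATOM     26  CA  GLY A  26       5.576 -14.703   0.000  1.00  0.00
ATOM     27  CA  GLY A  27       8.933 -12.941   0.000  1.00  0.00
ATOM     28  CA  GLY A  28      11.770 -10.427   0.000  1.00  0.00
ATOM     29  CA  GLY A  29      13.923  -7.308   0.000  1.00  0.00
ATOM     30  CA  CYS A  30      15.268  -3.763   0.000  1.00  0.00
ATOM     31  CA  GLY A  31      15.268  -3.763   3.800  1.00  0.00
ATOM     32  CA  GLY A  32      11.688  -2.486   3.800  1.00  0.00
ATOM     33  CA  GLY A  33       8.109  -1.210   3.800  1.00  0.00
ATOM     34  CA  GLY A  34       4.697   0.000   3.602  1.00  0.00
ATOM     35  CA  GLY A  35       4.306   0.000  -0.178  1.00  0.00
ATOM     36  CA  GLY A  36       3.931   0.000  -3.958  1.00  0.00
ATOM     37  CA  GLY A  37       3.931   0.000  -7.758  1.00  0.00
ATOM     38  CA  GLY A  38       3.931   0.000 -11.558  1.00  0.00
ATOM     39  CA  GLY A  39       3.931   0.000 -15.358  1.00  0.00
ATOM     40  CA  GLY A  40       3.931   0.000 -19.158  1.00  0.00
END
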