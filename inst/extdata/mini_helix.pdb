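ATOM      1  CA  HIS A   1       2.330  -0.094  -0.070  1.00  0.00              
ATOM      2  CA  TRP A   2      -0.600   2.241   1.333  1.00  0.00              
ATOM      3  CA  ARG A   3      -2.065  -0.695   2.967  1.00  0.00              
ATOM      4  CA  TYR A   4       0.924  -1.889   4.529  1.00  0.00              
ATOM      5  CA  ARG A   5       1.642   1.578   5.748  1.00  0.00              
ATOM      6  CA  ASN A   6      -1.587   1.543   7.294  1.00  0.00              
ATOM      7  CA  ASN A   7      -1.105  -1.983   9.072  1.00  0.00              
ATOM      8  CA  TRP A   8       2.013  -1.054  10.432  1.00  0.00              
ATOM      9  CA  ILE A   9       0.621   2.219  12.146  1.00  0.00              
ATOM     10  CA  MET A  10      -2.182   0.044  13.361  1.00  0.00              
ATOM     11  CA  PHE A  11       0.447  -2.318  14.911  1.00  0.00              
ATOM     12  CA  ASP A  12       2.146   0.804  16.605  1.00  0.00              
ATOM     13  CA  ARG A  13      -1.002   1.891  17.858  1.00  0.00              
ATOM     14  CA  THR A  14      -2.017  -1.690  19.429  1.00  0.00              
ATOM     15  CA  ARG A  15       2.006  -1.389  20.685  1.00  0.00              
ATOM     16  CA  TYR A  16       1.052   1.952  22.713  1.00  0.00              
ATOM     17  CA  ASP A  17      -2.384   0.763  23.987  1.00  0.00              
ATOM     18  CA  GLU A  18      -0.376  -2.302  25.354  1.00  0.00              
ATOM     19  CA  GLN A  19       2.072   0.086  27.174  1.00  0.00              
ATOM     20  CA  GLN A  20      -0.397   2.295  28.396  1.00  0.00              
END   
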