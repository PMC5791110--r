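@<TRIPOS>MOLECULE
pva_monomer
      9       8       0       0       0
@<TRIPOS>ATOM
      1 C           0.9885   -0.0785   -0.0609 C.3       1 UNL1       -0.0419 
      2 C           2.5028   -0.0770   -0.0680 C.3       1 UNL1        0.0414 
      3 O           2.9845    0.8697   -1.0102 O.3       1 UNL1       -0.3953 
      4 H           0.6037   -0.7968    0.6683 H         1 UNL1        0.0252 
      5 H           0.5965   -0.3366   -1.0502 H         1 UNL1        0.0252 
      6 H           0.6030    0.9164    0.1850 H         1 UNL1        0.0252 
      7 H           2.8942   -1.0646   -0.3307 H         1 UNL1        0.0554 
      8 H           2.8898    0.1962    0.9180 H         1 UNL1        0.0554 
      9 H           2.6449    0.6126   -1.8843 H         1 UNL1        0.2094 
@<TRIPOS>BOND
      1     1     2 1     
      2     2     3 1     
      3     1     4 1     
      4     1     5 1     
      5     1     6 1     
      6     2     7 1     
      7     2     8 1     
      8     3     9 1     
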