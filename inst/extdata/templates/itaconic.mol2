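@<TRIPOS>MOLECULE
itaconic
     13      12       0       0       0
@<TRIPOS>ATOM
      1 O           1.8602    0.4225    1.1259 O.co2     1 UNL1       -0.7460 
      2 C           2.2240    0.0659   -0.0378 C.2       1 UNL1        0.3605 
      3 O           1.8309    0.5461   -1.1462 O.co2     1 UNL1       -0.7460 
      4 C           3.1789   -1.1305   -0.1156 C.3       1 UNL1        0.0806 
      5 C           4.6785   -0.8764   -0.1030 C.2       1 UNL1        0.0444 
      6 C           5.2387    0.3447   -0.0415 C.2       1 UNL1       -0.0881 
      7 C           5.5985   -2.1379   -0.1660 C.2       1 UNL1        0.3826 
      8 O           5.0105   -3.2578   -0.2257 O.co2     1 UNL1       -0.7410 
      9 O           6.8500   -1.9191   -0.1535 O.co2     1 UNL1       -0.7410 
     10 H           2.9323   -1.6840   -1.0307 H         1 UNL1        0.0430 
     11 H           2.9349   -1.7930    0.7244 H         1 UNL1        0.0430 
     12 H           4.6361    1.2446    0.0037 H         1 UNL1        0.0540 
     13 H           6.3172    0.4587   -0.0352 H         1 UNL1        0.0540 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 1     
      5     5     6 2     
      6     5     7 1     
      7     7     8 ar    
      8     7     9 ar    
      9     4    10 1     
     10     4    11 1     
     11     6    12 1     
     12     6    13 1     
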