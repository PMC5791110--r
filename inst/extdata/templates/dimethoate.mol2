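@<TRIPOS>MOLECULE
dimethoate
     24      23       0       0       0
@<TRIPOS>ATOM
      1 C           1.8802    0.5802    0.4866 C.3       1 UNL1        0.0441 
      2 O           2.5785   -0.3648   -0.2948 O.3       1 UNL1       -0.3267 
      3 P           2.5825   -1.9433    0.0688 P.3       1 UNL1        0.2291 
      4 S           2.8552   -2.3220    1.9649 S.2       1 UNL1        0.0032 
      5 O           1.0939   -2.3264   -0.4631 O.3       1 UNL1       -0.3267 
      6 C           0.7157   -3.6885   -0.5392 C.3       1 UNL1        0.0441 
      7 S           3.9677   -2.8154   -1.2675 S.3       1 UNL1       -0.0646 
      8 C           4.6596   -1.4035   -2.1725 C.3       1 UNL1        0.0787 
      9 C           5.2844   -0.3357   -1.2779 C.2       1 UNL1        0.2231 
     10 O           5.2750    0.8493   -1.6038 O.2       1 UNL1       -0.2749 
     11 N           5.9149   -0.8000   -0.1468 N.am      1 UNL1       -0.3177 
     12 C           6.5596    0.0784    0.7978 C.3       1 UNL1        0.0001 
     13 H           2.6001    1.3140    0.8598 H         1 UNL1        0.0528 
     14 H           1.3565    0.1292    1.3314 H         1 UNL1        0.0528 
     15 H           1.1511    1.0948   -0.1437 H         1 UNL1        0.0528 
     16 H          -0.3703   -3.7430   -0.6544 H         1 UNL1        0.0528 
     17 H           0.9957   -4.2313    0.3668 H         1 UNL1        0.0528 
     18 H           1.1786   -4.1601   -1.4106 H         1 UNL1        0.0528 
     19 H           3.8552   -0.9461   -2.7546 H         1 UNL1        0.0476 
     20 H           5.4285   -1.7661   -2.8610 H         1 UNL1        0.0476 
     21 H           5.8995   -1.7951    0.0542 H         1 UNL1        0.1484 
     22 H           6.5731    1.1143    0.4473 H         1 UNL1        0.0426 
     23 H           7.5838   -0.2712    0.9460 H         1 UNL1        0.0426 
     24 H           6.0179    0.0214    1.7449 H         1 UNL1        0.0426 
@<TRIPOS>BOND
      1     1     2 1     
      2     2     3 1     
      3     3     4 2     
      4     3     5 1     
      5     5     6 1     
      6     3     7 1     
      7     7     8 1     
      8     8     9 1     
      9     9    10 2     
     10     9    11 am    
     11    11    12 1     
     12     1    13 1     
     13     1    14 1     
     14     1    15 1     
     15     6    16 1     
     16     6    17 1     
     17     6    18 1     
     18     8    19 1     
     19     8    20 1     
     20    11    21 1     
     21    12    22 1     
     22    12    23 1     
     23    12    24 1     
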