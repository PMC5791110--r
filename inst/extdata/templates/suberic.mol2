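@<TRIPOS>MOLECULE
suberic
     24      23       0       0       0
@<TRIPOS>ATOM
      1 O           4.2718   -0.1877    3.0945 O.co2     1 UNL1       -0.7462 
      2 C           4.0205   -0.2301    1.8528 C.2       1 UNL1        0.3560 
      3 O           3.2060   -0.9710    1.2382 O.co2     1 UNL1       -0.7464 
      4 C           4.8209    0.7750    1.0160 C.3       1 UNL1        0.0492 
      5 C           4.5130    0.8113   -0.4797 C.3       1 UNL1       -0.0428 
      6 C           5.3173    1.8746   -1.2393 C.3       1 UNL1       -0.0525 
      7 C           6.8413    1.6928   -1.2269 C.3       1 UNL1       -0.0525 
      8 C           7.3505    0.3712   -1.8129 C.3       1 UNL1       -0.0428 
      9 C           7.0178    0.1658   -3.2895 C.3       1 UNL1        0.0492 
     10 C           7.6709    1.1442   -4.2691 C.2       1 UNL1        0.3560 
     11 O           8.8234    1.5628   -3.9637 O.co2     1 UNL1       -0.7464 
     12 O           6.9880    1.3930   -5.3073 O.co2     1 UNL1       -0.7464 
     13 H           5.8800    0.5416    1.1716 H         1 UNL1        0.0379 
     14 H           4.6407    1.7704    1.4413 H         1 UNL1        0.0379 
     15 H           3.4457    1.0287   -0.6172 H         1 UNL1        0.0270 
     16 H           4.6783   -0.1765   -0.9245 H         1 UNL1        0.0270 
     17 H           5.0861    2.8599   -0.8153 H         1 UNL1        0.0265 
     18 H           4.9629    1.9083   -2.2771 H         1 UNL1        0.0265 
     19 H           7.2065    1.7834   -0.1981 H         1 UNL1        0.0265 
     20 H           7.2904    2.5293   -1.7748 H         1 UNL1        0.0265 
     21 H           6.9458   -0.4681   -1.2351 H         1 UNL1        0.0270 
     22 H           8.4378    0.3311   -1.6744 H         1 UNL1        0.0270 
     23 H           5.9313    0.1687   -3.4333 H         1 UNL1        0.0379 
     24 H           7.3603   -0.8345   -3.5820 H         1 UNL1        0.0379 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 1     
      5     5     6 1     
      6     6     7 1     
      7     7     8 1     
      8     8     9 1     
      9     9    10 1     
     10    10    11 ar    
     11    10    12 ar    
     12     4    13 1     
     13     4    14 1     
     14     5    15 1     
     15     5    16 1     
     16     6    17 1     
     17     6    18 1     
     18     7    19 1     
     19     7    20 1     
     20     8    21 1     
     21     8    22 1     
     22     9    23 1     
     23     9    24 1     
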