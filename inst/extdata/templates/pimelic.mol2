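@<TRIPOS>MOLECULE
pimelic
     21      20       0       0       0
@<TRIPOS>ATOM
      1 O           3.3155   -2.5426   -1.5278 O.co2     1 UNL1       -0.7463 
      2 C           4.5282   -2.1969   -1.6058 C.2       1 UNL1        0.3560 
      3 O           5.4853   -2.7719   -2.1965 O.co2     1 UNL1       -0.7464 
      4 C           4.8743   -0.8541   -0.9521 C.3       1 UNL1        0.0492 
      5 C           4.5570   -0.7819    0.5411 C.3       1 UNL1       -0.0428 
      6 C           5.3870   -1.7252    1.4210 C.3       1 UNL1       -0.0521 
      7 C           6.9059   -1.5237    1.3673 C.3       1 UNL1       -0.0428 
      8 C           7.3829   -0.1354    1.7909 C.3       1 UNL1        0.0492 
      9 C           7.1538    0.2582    3.2528 C.2       1 UNL1        0.3560 
     10 O           7.2129   -0.6733    4.1052 O.co2     1 UNL1       -0.7464 
     11 O           6.9886    1.4993    3.4490 O.co2     1 UNL1       -0.7464 
     12 H           4.2820   -0.0879   -1.4697 H         1 UNL1        0.0379 
     13 H           5.9238   -0.5981   -1.1355 H         1 UNL1        0.0379 
     14 H           3.4963   -1.0112    0.7006 H         1 UNL1        0.0270 
     15 H           4.6940    0.2504    0.8838 H         1 UNL1        0.0270 
     16 H           5.1651   -2.7624    1.1398 H         1 UNL1        0.0266 
     17 H           5.0472   -1.6163    2.4583 H         1 UNL1        0.0266 
     18 H           7.2650   -1.7268    0.3521 H         1 UNL1        0.0270 
     19 H           7.3763   -2.2815    2.0061 H         1 UNL1        0.0270 
     20 H           6.9467    0.6269    1.1341 H         1 UNL1        0.0379 
     21 H           8.4681   -0.0851    1.6324 H         1 UNL1        0.0379 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 1     
      5     5     6 1     
      6     6     7 1     
      7     7     8 1     
      8     8     9 1     
      9     9    10 ar    
     10     9    11 ar    
     11     4    12 1     
     12     4    13 1     
     13     5    14 1     
     14     5    15 1     
     15     6    16 1     
     16     6    17 1     
     17     7    18 1     
     18     7    19 1     
     19     8    20 1     
     20     8    21 1     
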