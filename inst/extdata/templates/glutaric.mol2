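@<TRIPOS>MOLECULE
glutaric
     15      14       0       0       0
@<TRIPOS>ATOM
      1 O           1.0834   -0.3397    0.0819 O.co2     1 UNL1       -0.7464 
      2 C           2.3176   -0.0681   -0.0481 C.2       1 UNL1        0.3560 
      3 O           2.8409    0.9645   -0.5475 O.co2     1 UNL1       -0.7464 
      4 C           3.2576   -1.1593    0.4815 C.3       1 UNL1        0.0497 
      5 C           4.7692   -0.9314    0.3710 C.3       1 UNL1       -0.0326 
      6 C           5.5577   -2.1138    0.9451 C.3       1 UNL1        0.0497 
      7 C           7.0908   -2.0488    0.9136 C.2       1 UNL1        0.3560 
      8 O           7.6230   -1.0215    0.4147 O.co2     1 UNL1       -0.7464 
      9 O           7.6621   -3.0696    1.4092 O.co2     1 UNL1       -0.7464 
     10 H           2.9993   -2.0855   -0.0485 H         1 UNL1        0.0379 
     11 H           2.9993   -1.3158    1.5371 H         1 UNL1        0.0379 
     12 H           5.0434   -0.0125    0.9023 H         1 UNL1        0.0276 
     13 H           5.0435   -0.7806   -0.6797 H         1 UNL1        0.0276 
     14 H           5.2676   -3.0267    0.4088 H         1 UNL1        0.0379 
     15 H           5.2676   -2.2569    1.9942 H         1 UNL1        0.0379 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 1     
      5     5     6 1     
      6     6     7 1     
      7     7     8 ar    
      8     7     9 ar    
      9     4    10 1     
     10     4    11 1     
     11     5    12 1     
     12     5    13 1     
     13     6    14 1     
     14     6    15 1     
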