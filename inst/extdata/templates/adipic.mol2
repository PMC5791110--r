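@<TRIPOS>MOLECULE
adipic
     18      17       0       0       0
@<TRIPOS>ATOM
      1 O           3.1575    2.7012   -0.9722 O.co2     1 UNL1       -0.7466 
      2 C           2.5284    2.2311    0.0187 C.2       1 UNL1        0.3560 
      3 O           1.4274    2.6224    0.5093 O.co2     1 UNL1       -0.7464 
      4 C           3.1182    0.9747    0.6696 C.3       1 UNL1        0.0492 
      5 C           4.6362    0.8033    0.6207 C.3       1 UNL1       -0.0423 
      6 C           5.4348    1.8343    1.4285 C.3       1 UNL1       -0.0423 
      7 C           5.1517    1.8429    2.9302 C.3       1 UNL1        0.0492 
      8 C           5.5654    0.6040    3.7297 C.2       1 UNL1        0.3560 
      9 O           6.5842   -0.0178    3.3138 O.co2     1 UNL1       -0.7464 
     10 O           4.8740    0.3784    4.7678 O.co2     1 UNL1       -0.7464 
     11 H           2.6685    0.1285    0.1341 H         1 UNL1        0.0379 
     12 H           2.7660    0.8973    1.7040 H         1 UNL1        0.0379 
     13 H           4.9729    0.8490   -0.4230 H         1 UNL1        0.0271 
     14 H           4.8876   -0.2035    0.9756 H         1 UNL1        0.0271 
     15 H           5.2379    2.8361    1.0262 H         1 UNL1        0.0271 
     16 H           6.5035    1.6464    1.2618 H         1 UNL1        0.0271 
     17 H           4.0935    2.0622    3.1101 H         1 UNL1        0.0379 
     18 H           5.7109    2.6788    3.3711 H         1 UNL1        0.0379 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 1     
      5     5     6 1     
      6     6     7 1     
      7     7     8 1     
      8     8     9 ar    
      9     8    10 ar    
     10     4    11 1     
     11     4    12 1     
     12     5    13 1     
     13     5    14 1     
     14     6    15 1     
     15     6    16 1     
     16     7    17 1     
     17     7    18 1     
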