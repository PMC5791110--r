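@<TRIPOS>MOLECULE
azelaic
     27      26       0       0       0
@<TRIPOS>ATOM
      1 O           5.1916    1.5042    5.2976 O.co2     1 UNL1       -0.7460 
      2 C           4.9085    0.3236    4.9305 C.2       1 UNL1        0.3560 
      3 O           4.3168   -0.5846    5.5738 O.co2     1 UNL1       -0.7464 
      4 C           5.3536   -0.0085    3.5035 C.3       1 UNL1        0.0492 
      5 C           5.0080   -1.4015    2.9816 C.3       1 UNL1       -0.0428 
      6 C           5.4744   -1.6284    1.5370 C.3       1 UNL1       -0.0526 
      7 C           6.9923   -1.5398    1.3274 C.3       1 UNL1       -0.0530 
      8 C           7.8157   -2.5588    2.1240 C.3       1 UNL1       -0.0526 
      9 C           7.5080   -4.0298    1.8143 C.3       1 UNL1       -0.0428 
     10 C           7.8012   -4.4024    0.3636 C.3       1 UNL1        0.0492 
     11 C           7.5413   -5.8564   -0.0400 C.2       1 UNL1        0.3560 
     12 O           7.0774   -6.6244    0.8458 O.co2     1 UNL1       -0.7464 
     13 O           7.8368   -6.1177   -1.2446 O.co2     1 UNL1       -0.7464 
     14 H           6.4392    0.1393    3.4790 H         1 UNL1        0.0379 
     15 H           4.9076    0.7411    2.8375 H         1 UNL1        0.0379 
     16 H           3.9201   -1.5384    3.0166 H         1 UNL1        0.0270 
     17 H           5.4296   -2.1687    3.6407 H         1 UNL1        0.0270 
     18 H           4.9913   -0.8889    0.8874 H         1 UNL1        0.0265 
     19 H           5.1125   -2.6063    1.1957 H         1 UNL1        0.0265 
     20 H           7.3416   -0.5313    1.5793 H         1 UNL1        0.0265 
     21 H           7.2035   -1.6512    0.2575 H         1 UNL1        0.0265 
     22 H           7.6752   -2.3848    3.1987 H         1 UNL1        0.0265 
     23 H           8.8817   -2.3707    1.9292 H         1 UNL1        0.0265 
     24 H           6.4632   -4.2551    2.0611 H         1 UNL1        0.0270 
     25 H           8.1160   -4.6549    2.4782 H         1 UNL1        0.0270 
     26 H           8.8547   -4.1847    0.1473 H         1 UNL1        0.0379 
     27 H           7.1967   -3.7845   -0.3095 H         1 UNL1        0.0379 
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
     10    10    11 1     
     11    11    12 ar    
     12    11    13 ar    
     13     4    14 1     
     14     4    15 1     
     15     5    16 1     
     16     5    17 1     
     17     6    18 1     
     18     6    19 1     
     19     7    20 1     
     20     7    21 1     
     21     8    22 1     
     22     8    23 1     
     23     9    24 1     
     24     9    25 1     
     25    10    26 1     
     26    10    27 1     
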