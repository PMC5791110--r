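@<TRIPOS>MOLECULE
citraconic
     13      12       0       0       0
@<TRIPOS>ATOM
      1 O           1.1566   -0.3080    0.6967 O.co2     1 UNL1       -0.7411 
      2 C           2.1809    0.0517    0.0271 C.2       1 UNL1        0.3826 
      3 O           2.3787   -0.0564   -1.2146 O.co2     1 UNL1       -0.7410 
      4 C           3.1738    0.9531    0.8260 C.2       1 UNL1        0.0445 
      5 C           2.5163    1.9792    1.7103 C.3       1 UNL1       -0.0326 
      6 C           4.5206    0.9416    0.7782 C.2       1 UNL1        0.0365 
      7 C           5.5573    0.0751    0.0590 C.2       1 UNL1        0.3800 
      8 O           5.3526   -1.1669   -0.0095 O.co2     1 UNL1       -0.7412 
      9 O           6.6303    0.7090   -0.2094 O.co2     1 UNL1       -0.7412 
     10 H           1.4260    1.9884    1.6188 H         1 UNL1        0.0280 
     11 H           2.8613    2.9878    1.4544 H         1 UNL1        0.0280 
     12 H           2.7606    1.7835    2.7607 H         1 UNL1        0.0280 
     13 H           5.0439    1.6906    1.3733 H         1 UNL1        0.0695 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 1     
      5     4     6 2     
      6     6     7 1     
      7     7     8 ar    
      8     7     9 ar    
      9     5    10 1     
     10     5    11 1     
     11     5    12 1     
     12     6    13 1     
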