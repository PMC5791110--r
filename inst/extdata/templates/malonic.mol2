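@<TRIPOS>MOLECULE
malonic
      9       8       0       0       0
@<TRIPOS>ATOM
      1 O           1.9818    1.0478    0.5436 O.co2     1 UNL1       -0.7458 
      2 C           2.3659   -0.0080   -0.0564 C.2       1 UNL1        0.3668 
      3 O           1.9538   -1.1946    0.1577 O.co2     1 UNL1       -0.7458 
      4 C           3.1346    0.2008   -1.3331 C.3       1 UNL1        0.1504 
      5 C           4.6293    0.1624   -1.1414 C.2       1 UNL1        0.3668 
      6 O           5.1381   -0.0538   -0.0104 O.co2     1 UNL1       -0.7458 
      7 O           5.2716    0.3649   -2.2299 O.co2     1 UNL1       -0.7458 
      8 H           2.8578    1.1660   -1.7728 H         1 UNL1        0.0496 
      9 H           2.8534   -0.5734   -2.0576 H         1 UNL1        0.0496 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 1     
      5     5     6 ar    
      6     5     7 ar    
      7     4     8 1     
      8     4     9 1     
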