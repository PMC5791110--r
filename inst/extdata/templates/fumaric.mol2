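@<TRIPOS>MOLECULE
fumaric
     10       9       0       0       0
@<TRIPOS>ATOM
      1 O           1.0508   -0.0272   -0.0716 O.co2     1 UNL1       -0.7409 
      2 C           2.3103    0.0897    0.0369 C.2       1 UNL1        0.3797 
      3 O           2.9618    0.8840    0.7745 O.co2     1 UNL1       -0.7413 
      4 C           3.1117   -0.8681   -0.8524 C.2       1 UNL1        0.0335 
      5 C           4.4563   -0.9342   -0.9138 C.2       1 UNL1        0.0335 
      6 C           5.2577   -1.8919   -1.8031 C.2       1 UNL1        0.3797 
      7 O           4.6062   -2.6862   -2.5407 O.co2     1 UNL1       -0.7413 
      8 O           6.5172   -1.7750   -1.6946 O.co2     1 UNL1       -0.7413 
      9 H           2.5287   -1.5406   -1.4769 H         1 UNL1        0.0692 
     10 H           5.0394   -0.2616   -0.2893 H         1 UNL1        0.0692 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 2     
      5     5     6 1     
      6     6     7 ar    
      7     6     8 ar    
      8     4     9 1     
      9     5    10 1     
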