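@<TRIPOS>MOLECULE
tartaric
     14      13       0       0       0
@<TRIPOS>ATOM
      1 O           1.1161   -0.4762    0.2510 O.co2     1 UNL1       -0.7435 
      2 C           2.2185    0.0375   -0.1108 C.2       1 UNL1        0.3871 
      3 O           2.6203    1.2322    0.0549 O.co2     1 UNL1       -0.7433 
      4 C           3.1111   -0.8421   -1.0473 C.3       1 UNL1        0.1924 
      5 O           2.9322   -0.3630   -2.4206 O.3       1 UNL1       -0.3778 
      6 C           4.6074   -0.7667   -0.7435 C.3       1 UNL1        0.1924 
      7 O           5.1121    0.5809   -0.9846 O.3       1 UNL1       -0.3778 
      8 C           4.9463   -1.2686    0.6890 C.2       1 UNL1        0.3871 
      9 O           4.7384   -2.5053    0.8950 O.co2     1 UNL1       -0.7433 
     10 O           5.4948   -0.4284    1.4647 O.co2     1 UNL1       -0.7433 
     11 H           2.7606   -1.8794   -1.0175 H         1 UNL1        0.0744 
     12 H           3.1764    0.5815   -2.3116 H         1 UNL1        0.2106 
     13 H           5.1499   -1.3986   -1.4576 H         1 UNL1        0.0744 
     14 H           4.7753    1.0562   -0.1876 H         1 UNL1        0.2106 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 1     
      5     4     6 1     
      6     6     7 1     
      7     6     8 1     
      8     8     9 ar    
      9     8    10 ar    
     10     4    11 1     
     11     5    12 1     
     12     6    13 1     
     13     7    14 1     
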