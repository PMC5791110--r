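@<TRIPOS>MOLECULE
succinic
     12      11       0       0       0
@<TRIPOS>ATOM
      1 O           1.0109    0.0569    0.0126 O.co2     1 UNL1       -0.7462 
      2 C           2.2694   -0.1145   -0.0080 C.2       1 UNL1        0.3565 
      3 O           2.8984   -1.2021   -0.1473 O.co2     1 UNL1       -0.7464 
      4 C           3.0927    1.1679    0.1582 C.3       1 UNL1        0.0594 
      5 C           4.6149    1.0318    0.1406 C.3       1 UNL1        0.0594 
      6 C           5.4382    2.3139    0.3087 C.2       1 UNL1        0.3565 
      7 O           4.8092    3.4012    0.4510 O.co2     1 UNL1       -0.7464 
      8 O           6.6967    2.1428    0.2863 O.co2     1 UNL1       -0.7464 
      9 H           2.7876    1.6308    1.1055 H         1 UNL1        0.0384 
     10 H           2.7877    1.8570   -0.6398 H         1 UNL1        0.0384 
     11 H           4.9200    0.5702   -0.8073 H         1 UNL1        0.0384 
     12 H           4.9198    0.3417    0.9377 H         1 UNL1        0.0384 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 1     
      5     5     6 1     
      6     6     7 ar    
      7     6     8 ar    
      8     4     9 1     
      9     4    10 1     
     10     5    11 1     
     11     5    12 1     
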