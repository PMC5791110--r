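@<TRIPOS>MOLECULE
malic
     13      12       0       0       0
@<TRIPOS>ATOM
      1 O           2.1889   -0.8909    0.6261 O.co2     1 UNL1       -0.7434 
      2 C           2.5207    0.0999   -0.1100 C.2       1 UNL1        0.3845 
      3 O           2.2891    0.2863   -1.3371 O.co2     1 UNL1       -0.7434 
      4 C           3.2548    1.2434    0.6748 C.3       1 UNL1        0.1659 
      5 O           2.8881    1.1167    2.0756 O.3       1 UNL1       -0.3799 
      6 C           4.7512    1.0212    0.5137 C.3       1 UNL1        0.0857 
      7 C           5.6228    2.1353    1.0844 C.2       1 UNL1        0.3590 
      8 O           5.4203    3.3017    0.6352 O.co2     1 UNL1       -0.7463 
      9 O           6.5386    1.7564    1.8800 O.co2     1 UNL1       -0.7463 
     10 H           2.9258    2.2252    0.3216 H         1 UNL1        0.0717 
     11 H           2.6337    0.1656    2.1215 H         1 UNL1        0.2105 
     12 H           5.0044    0.9449   -0.5519 H         1 UNL1        0.0410 
     13 H           5.0404    0.0694    0.9772 H         1 UNL1        0.0410 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 1     
      5     4     6 1     
      6     6     7 1     
      7     7     8 ar    
      8     7     9 ar    
      9     4    10 1     
     10     5    11 1     
     11     6    12 1     
     12     6    13 1     
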