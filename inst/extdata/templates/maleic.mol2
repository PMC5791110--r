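@<TRIPOS>MOLECULE
maleic
     10       9       0       0       0
@<TRIPOS>ATOM
      1 O           0.9679   -0.5899   -0.0397 O.co2     1 UNL1       -0.7409 
      2 C           2.0493    0.0736    0.1005 C.2       1 UNL1        0.3797 
      3 O           2.2508    1.0943    0.8086 O.co2     1 UNL1       -0.7413 
      4 C           3.1305   -0.3394   -0.9119 C.2       1 UNL1        0.0335 
      5 C           4.4744   -0.3174   -0.9181 C.2       1 UNL1        0.0335 
      6 C           5.5493    0.0863    0.1024 C.2       1 UNL1        0.3797 
      7 O           5.3490   -0.1770    1.3164 O.co2     1 UNL1       -0.7413 
      8 O           6.6274    0.4846   -0.4523 O.co2     1 UNL1       -0.7413 
      9 H           2.6570   -0.7283   -1.8125 H         1 UNL1        0.0692 
     10 H           4.9503   -0.6521   -1.8386 H         1 UNL1        0.0692 
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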