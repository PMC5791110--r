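@<TRIPOS>MOLECULE
oxalic
      6       5       0       0       0
@<TRIPOS>ATOM
      1 O           1.0638    0.0149    0.1768 O.co2     1 UNL1       -0.7329 
      2 C           2.3394   -0.0442    0.0664 C.2       1 UNL1        0.4661 
      3 O           3.0356   -0.5508   -0.8832 O.co2     1 UNL1       -0.7331 
      4 C           3.1348    0.5699    1.2181 C.2       1 UNL1        0.4661 
      5 O           3.4233    1.8127    1.0951 O.co2     1 UNL1       -0.7331 
      6 O           3.4256   -0.2254    2.1802 O.co2     1 UNL1       -0.7331 
@<TRIPOS>BOND
      1     1     2 ar    
      2     2     3 ar    
      3     2     4 1     
      4     4     5 ar    
      5     4     6 ar    
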