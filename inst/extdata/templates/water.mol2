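@<TRIPOS>MOLECULE
water
      3       2       0       0       0
@<TRIPOS>ATOM
      1 O           0.9643    0.0860   -0.0701 O.3       1 HOH1       -0.4104 
      2 H           1.9322    0.0398   -0.0742 H         0 HOH0        0.2052 
      3 H           0.6854   -0.8384   -0.1521 H         0 HOH0        0.2052 
@<TRIPOS>BOND
      1     1     2 1     
      2     1     3 1     
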