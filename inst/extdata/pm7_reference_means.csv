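id,acid,mean_kcal_mol
1,oxalic,-1.861
2,malonic,-1.952
3,succinic,-1.955
4,malic,-1.998
5,fumaric,-1.994
6,maleic,-1.964
7,citraconic,-1.993
8,itaconic,-1.988
9,tartaric,-1.879
10,glutaric,-1.961
11,adipic,-1.985
12,pimelic,-1.975
13,suberic,-1.969
14,azelaic,-1.924
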