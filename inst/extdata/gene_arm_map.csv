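arm,gene
1q,MCL1
1q,CKS1B
18q,BCL2
3q,BCL6
8q,MYC
9p,CDKN2A
17p,TP53
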