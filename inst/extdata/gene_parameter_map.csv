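gene,parameter_id,direction,network,proxy_note
MYD88,nemo_act,up,both,NF-kB pathway input; activating mutations raise NEMO:IKK activity
CD79B,nemo_act,up,both,BCR signalling to NEMO:IKK
CARD11,nemo_act,up,both,CBM complex; modelled as increased NEMO:IKK activity
TNFAIP3,nemo_act,down,both,A20 negative regulator of NF-kB; loss raises NEMO:IKK
BCL2,tr_bcl2,up,apoptosis,direct target: BCL2 transcription rate
MCL1,tr_bcl2,up,apoptosis,modelled as BCL2 overexpression (closest modelled species)
BAX,s_act,up,apoptosis,pro-apoptotic effector; mapped to activator synthesis
TP53,s_act,up,apoptosis,p53 drives pro-apoptotic activator expression; loss halves it
MYC,tr_myc,up,proliferation,direct target: MYC transcription rate
CCND1,tr_cycd,up,proliferation,cyclin D transcription
CCND2,tr_cycd,up,proliferation,cyclin D transcription
CCND3,tr_cycd,up,proliferation,cyclin D transcription
CKS1B,cks1b_act,up,proliferation,Cks1/SCF-mediated p27 degradation
CDKN1B,ks_p27,up,proliferation,p27 itself; loss halves p27 synthesis
CDKN2A,ks_p27,up,proliferation,CDK inhibitor mapped to the p27 axis (closest modelled species)
BCL6,tr_bcl6,up,other,differentiation repressor (Blimp1 axis)
IRF4,tr_irf4,up,other,NF-kB target feeding the Blimp1 switch
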