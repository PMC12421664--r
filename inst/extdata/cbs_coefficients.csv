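family,X,Y,alpha,beta
cc,2,3,4.420,2.460
cc,3,4,5.460,3.050
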