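model,classes,n_par,LL,CAIC
rmGPCM,1,55,-69917,140376
rmGPCM,2,107,-68382,137819
rmGPCM,3,159,-68035,137637
rmGPCM,4,211,-67877,137833
rmGPCM,5,263,-67736,138065
mPCM,3,155,-68173,137873
mGPCM,3,169,-68009,137684
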