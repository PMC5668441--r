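drug,channel,genotype,IC50_uM,hill
mexiletine,I_Na,control,43,1
mexiletine,I_Na,V1763M,18,1
mexiletine,I_NaL,any,9,1
mexiletine,I_Kr,any,50,1
mexiletine,I_CaL,any,125,1
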