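drug,channel,genotype,IC50_uM,hill
ranolazine,I_Na,any,135,1
ranolazine,I_NaL,any,7,1
ranolazine,I_Kr,any,12,1
ranolazine,I_CaL,any,300,1
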