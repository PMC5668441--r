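drug,channel,genotype,IC50_uM,hill
testdrug,I_NaL,any,20,1
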