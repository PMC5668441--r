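biomarker,lower,upper,source
rate,15,95,synthetic
MDP,-86,-60,synthetic
Peak,10,45,synthetic
APA,75,125,synthetic
Vmax,5,80,synthetic
APD30,80,440,synthetic
APD50,120,520,synthetic
APD90,150,600,synthetic
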