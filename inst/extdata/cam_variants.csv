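name,kd_ca_uM,disease,cdi_factor
WT,2.5,none,1.0
N54I,3.1,CPVT4,NA
D96V,38.0,LQT14,NA
N98S,11.0,CPVT4;LQT14,NA
D130G,150.0,LQT14,NA
F142L,15.0,LQT14,NA
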