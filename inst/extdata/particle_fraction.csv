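congener,particle_fraction
Nap,0.05
Acy,0.05
Ace,0.05
Fluo,0.05
Phe,0.05
Ant,0.05
Flu,0.05
Pyr,0.05
Chry,0.5
BaA,0.5
BbF,1
BkF,1
BaP,1
DBA,1
IP,1
BghiP,1
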