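location,mean,sd
forehead,1.65,0.174
cheek,1.53,0.173
ventral forearm,1.46,0.115
palm,1.45,0.0813
back,1.42,0.154
upper arm,1.41,0.120
dorsal forearm,1.38,0.120
neck,1.31,0.117
shin,1.30,0.141
chest,1.28,0.141
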