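location1,location2,p,censored,significant
forehead,cheek,0.36,FALSE,FALSE
forehead,ventral forearm,0.008,FALSE,TRUE
forehead,palm,0.004,FALSE,TRUE
forehead,back,0.001,TRUE,TRUE
forehead,upper arm,0.001,TRUE,TRUE
forehead,dorsal forearm,0.001,TRUE,TRUE
forehead,neck,0.001,TRUE,TRUE
forehead,shin,0.001,TRUE,TRUE
forehead,chest,0.001,TRUE,TRUE
cheek,ventral forearm,0.94,FALSE,FALSE
cheek,palm,0.88,FALSE,FALSE
cheek,back,0.48,FALSE,FALSE
cheek,upper arm,0.27,FALSE,FALSE
cheek,dorsal forearm,0.094,FALSE,FALSE
cheek,neck,0.001,TRUE,TRUE
cheek,shin,0.001,TRUE,TRUE
cheek,chest,0.001,TRUE,TRUE
ventral forearm,palm,1.0,FALSE,FALSE
ventral forearm,back,1.0,FALSE,FALSE
ventral forearm,upper arm,0.98,FALSE,FALSE
ventral forearm,dorsal forearm,0.86,FALSE,FALSE
ventral forearm,neck,0.062,FALSE,FALSE
ventral forearm,shin,0.0367,FALSE,TRUE
ventral forearm,chest,0.0128,FALSE,TRUE
palm,back,1.0,FALSE,FALSE
palm,upper arm,0.99,FALSE,FALSE
palm,dorsal forearm,0.92,FALSE,FALSE
palm,neck,0.096,FALSE,FALSE
palm,shin,0.059,FALSE,FALSE
palm,chest,0.0219,FALSE,TRUE
back,upper arm,1.0,FALSE,FALSE
back,dorsal forearm,1.0,FALSE,FALSE
back,neck,0.39,FALSE,FALSE
back,shin,0.29,FALSE,FALSE
back,chest,0.143,FALSE,FALSE
upper arm,dorsal forearm,1.0,FALSE,FALSE
upper arm,neck,0.62,FALSE,FALSE
upper arm,shin,0.50,FALSE,FALSE
upper arm,chest,0.29,FALSE,FALSE
dorsal forearm,neck,0.89,FALSE,FALSE
dorsal forearm,shin,0.80,FALSE,FALSE
dorsal forearm,chest,0.60,FALSE,FALSE
neck,shin,1.0,FALSE,FALSE
neck,chest,1.0,FALSE,FALSE
shin,chest,1.0,FALSE,FALSE
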