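element,IP,EA,radius,mass,logp_contrib,hbd,hba
H,13.598,0.754,1.20,1.008,0.11,FALSE,FALSE
C,11.260,1.260,1.70,12.011,0.18,FALSE,FALSE
N,14.534,-0.070,1.55,14.007,-0.60,TRUE,TRUE
O,13.618,1.461,1.52,15.999,-0.45,TRUE,TRUE
F,17.423,3.401,1.47,18.998,0.21,FALSE,TRUE
S,10.360,2.077,1.80,32.060,0.25,FALSE,FALSE
Cl,12.968,3.613,1.75,35.450,0.52,FALSE,FALSE
Br,11.814,3.364,1.85,79.904,0.70,FALSE,FALSE
I,10.451,3.059,1.98,126.904,0.90,FALSE,FALSE
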