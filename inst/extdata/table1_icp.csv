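protein,prep,Zn,Cd,Cu
BgwtMT,Zn,9.8,0,0
BgKNMT,Zn,9.4,0,0
BgwtMT,Cd,0,12.9,0
BgKNMT,Cd,0,13.3,0
BgwtMT,Cu,3.7,0,9.5
BgKNMT,Cu,1.9,0,9.9
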