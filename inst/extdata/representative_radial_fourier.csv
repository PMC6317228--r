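harmonic,a,b
0,0.9490,0
1,0.5150,0.5873
2,0.2893,0.1871
3,0.2838,0.0459
4,0.1498,-0.0032
5,0.1227,-0.1109
6,0.1177,-0.0743
7,0.0569,-0.0196
8,0.0105,-0.0086
9,0.0008,-0.0043
10,0.0056,-0.0007
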