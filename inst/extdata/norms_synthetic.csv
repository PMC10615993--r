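token,frequency,prevalence,aoa
cat,3.2,2.5,3.1
dog,3.3,2.5,3.0
letter,2.9,2.4,5.2
stamp,2.1,2.2,6.0
alien,2.0,2.1,7.5
grandmother,2.4,2.4,4.0
wrote,2.8,2.4,5.5
sent,3.0,2.4,4.8
story,3.1,2.5,4.5
space,2.9,2.4,5.0
ship,2.7,2.4,4.6
moon,2.8,2.5,4.2
sun,3.0,2.5,3.5
ocean,2.6,2.4,5.1
whale,2.2,2.3,5.4
piano,2.3,2.3,5.8
music,3.0,2.5,4.4
danced,2.5,2.3,4.9
galaxy,2.0,2.1,8.0
postage,1.6,1.9,8.5
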