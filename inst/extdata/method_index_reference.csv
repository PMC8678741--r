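method,di,ri,dei
Den,0.959,0.681,1.409
Fur,0.905,0.779,1.161
Ref,0.986,0.492,2.004
Per,0.881,0.730,1.207
Org,0.762,0.583,1.307
Com,0.925,0.633,1.461
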