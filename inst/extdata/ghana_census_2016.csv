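region,category,count
Ghana,CHPS,4449
Ghana,HCA,903
Ghana,HCB,158
Ghana,PolyC,40
Ghana,PHA,96
Ghana,PHB,49
Ghana,PHC,29
Ghana,PHD,14
Ghana,RH,7
Ghana,EmTH,2
Ghana,EsTH,2
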