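((((((Osativa:0.002022,Orufipogon:0.003527):0.000373,Onivara:0.002659):0.001616,(Obarthii:0.001242,Oglaberrima:0.001793):0.001899):0.001268,Oglumaepatula:0.004631):0.007018,Olongistaminata:0.011113):0.003953,Omeridionalis:0.014768);
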