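taxon,c0,c1,c2,ln_b0,a,E
Oribatida,-2.5,1.0,2.0,23.0,0.7,0.69
Collembola,-2.3,1.1,1.9,23.0,0.7,0.69
Symphyla,-2.4,1.2,1.8,23.0,0.7,0.69
Protura,-2.6,1.0,2.0,23.0,0.7,0.69
Annelida,-1.8,1.3,1.7,23.0,0.7,0.69
Blattodea,-2.0,1.2,1.8,23.0,0.7,0.69
Diplopoda,-1.9,1.2,1.8,23.0,0.7,0.69
Isopoda,-2.0,1.2,1.8,23.0,0.7,0.69
Isoptera,-2.2,1.1,1.9,23.0,0.7,0.69
Psocoptera,-2.4,1.0,2.0,23.0,0.7,0.69
Hemiptera,-2.1,1.1,1.9,23.0,0.7,0.69
Lepidoptera,-2.0,1.2,1.8,23.0,0.7,0.69
Orthoptera,-1.9,1.3,1.7,23.0,0.7,0.69
Thysanoptera,-2.5,1.0,2.0,23.0,0.7,0.69
Diptera,-2.2,1.1,1.9,23.0,0.7,0.69
Coleoptera,-2.0,1.2,1.8,23.0,0.7,0.69
Pseudoscorpiones,-2.3,1.1,1.9,23.0,0.7,0.69
Mesostigmata,-2.5,1.0,2.0,23.0,0.7,0.69
Diplura,-2.3,1.1,1.9,23.0,0.7,0.69
Formicidae,-2.1,1.1,1.9,23.0,0.7,0.69
Chilopoda,-2.0,1.2,1.8,23.0,0.7,0.69
Araneae,-2.2,1.1,1.9,23.0,0.7,0.69
Pauropoda,-2.6,1.0,2.0,23.0,0.7,0.69
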