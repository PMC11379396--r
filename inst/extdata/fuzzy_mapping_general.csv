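set,species,factor,reversed
Confident,rhesus,Confident,TRUE
Confident,longtailed,Confident,FALSE
Confident,bonnet,Confident,FALSE
Sociable,rhesus,Sociable,FALSE
Sociable,longtailed,Sociable,FALSE
Sociable,bonnet,Sociable,FALSE
Active,rhesus,Active,TRUE
Active,longtailed,Active,FALSE
Active,bonnet,Active,FALSE
Irritable,rhesus,Irritable,FALSE
Irritable,longtailed,Irritable/Equable,FALSE
Irritable,bonnet,Equable,FALSE
Equable,rhesus,Equable,TRUE
Equable,longtailed,Irritable/Equable,FALSE
Equable,bonnet,Equable,FALSE
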