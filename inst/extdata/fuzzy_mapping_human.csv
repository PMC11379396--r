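set,species,factor,reversed
Exploratory,rhesus,Exploratory,FALSE
Exploratory,longtailed,Exploratory,FALSE
Exploratory,bonnet,Lazy/Exploratory,TRUE
Apprehensive,rhesus,Apprehensive,TRUE
Apprehensive,longtailed,Apprehensive,FALSE
Apprehensive,bonnet,Apprehensive,FALSE
Lazy,rhesus,Lazy,FALSE
Lazy,longtailed,Lazy,FALSE
Lazy,bonnet,Lazy/Exploratory,FALSE
Irritable,rhesus,Irritable,FALSE
Irritable,longtailed,Irritable,FALSE
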