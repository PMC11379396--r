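species,item,stage
rhesus,Reckless,Low ICC
rhesus,Unemotional,Low ICC
rhesus,Sensitive,Low ICC
rhesus,Vigilant,Low ICC
rhesus,Tense,Low Communality
rhesus,Eccentric,Low Communality
longtailed,Excitable,Low ICC
longtailed,Unpredictable,Low ICC
longtailed,Sensitive,Low ICC
longtailed,Intelligent,Low Communality
longtailed,Eccentric,Low Communality
longtailed,Vigilant,Low Communality
bonnet,Fearful,Low ICC
bonnet,Insecure,Low ICC
bonnet,Independent,Low ICC
bonnet,Tolerant,Low ICC
bonnet,Sensitive,Low ICC
bonnet,Vigilant,Low ICC
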