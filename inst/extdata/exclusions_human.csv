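species,item,stage
rhesus,Submissive/subordinate,Low ICC
rhesus,Tense,Low ICC
rhesus,Affiliative/Companionable,Low ICC
rhesus,Sensitive,Low ICC
rhesus,Sociable,Low Communality
rhesus,Solitary,Low Communality
longtailed,Eccentric,Low Communality
longtailed,Sensitive,Low Communality
bonnet,Irritable,Low ICC
bonnet,Aggressive,Low ICC
bonnet,Excitable,Low ICC
bonnet,Feisty,Low ICC
bonnet,Unemotional,Low ICC
bonnet,Tolerant,Low ICC
bonnet,Gentle,Low ICC
bonnet,Calm/Equable,Low ICC
bonnet,Equable,Low ICC
bonnet,Vigilant,Low ICC
bonnet,Intelligent,Low ICC
bonnet,Impulsive,Low ICC
bonnet,Eccentric,Low ICC
bonnet,Unpredictable,Low ICC
bonnet,Strong,Low ICC
bonnet,Bold,Low ICC
bonnet,Independent,Low ICC
bonnet,Insecure,Low ICC
bonnet,Affiliative/Companionable,Low ICC
bonnet,Sensitive,Low ICC
bonnet,Understanding,Low Communality
bonnet,Fearful,Low Communality
bonnet,Sociable,Low MSA
bonnet,Solitary,Low MSA
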