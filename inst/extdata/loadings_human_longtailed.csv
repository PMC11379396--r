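item,Apprehensive,Exploratory,Irritable,Lazy
Irritable,0.03,-0.04,0.89,0.08
Aggressive,-0.27,0.09,0.84,0.14
Excitable,0.20,0.28,0.66,-0.30
Feisty,-0.22,0.02,0.84,0.05
Bullying,-0.38,0.31,0.58,0.12
Reckless,-0.10,0.52,0.46,-0.07
Defiant,-0.19,0.54,0.48,0.01
Unemotional,-0.44,0.01,-0.51,0.36
Understanding,-0.24,0.10,-0.67,-0.11
Tolerant,-0.12,0.69,-0.55,0.17
Gentle,0.27,0.47,-0.59,0.19
Calm/Equable,-0.25,0.18,-0.76,0.23
Equable,-0.23,0.23,-0.69,0.32
Curious/exploratory/inquisitive,-0.16,0.78,-0.01,-0.17
Vigilant,-0.13,0.37,0.18,-0.47
Intelligent,-0.41,0.34,-0.08,-0.32
Opportunistic,-0.25,0.65,0.06,-0.15
Active/Energetic,-0.08,0.72,0.08,-0.27
Impulsive,0.05,0.54,0.52,-0.06
Unpredictable,0.05,0.35,0.55,-0.26
Persistent,-0.33,0.62,0.18,-0.01
Confident,-0.75,0.31,0.07,-0.01
Strong,-0.52,0.13,0.33,0.20
Bold,-0.64,0.38,0.13,-0.07
Effective,-0.59,0.42,0.18,0.09
Direct/forceful/gets own way,-0.56,0.42,0.28,0.16
Independent,-0.29,0.18,0.32,0.50
Insecure,0.61,-0.02,-0.12,-0.32
Cautious,0.74,-0.25,-0.10,0.00
Timid,0.84,-0.10,-0.07,0.08
Nervous/anxious/not calm,0.79,0.19,0.40,-0.13
Fearful,0.89,-0.05,0.10,0.11
Apprehensive,0.89,-0.02,0.08,0.15
Lazy,0.27,-0.33,-0.09,0.61
Slow,-0.06,-0.16,-0.22,0.72
Depressed,0.64,0.02,0.22,0.51
Submissive/subordinate,0.92,0.08,-0.11,-0.14
Tense,0.44,-0.14,0.37,0.38
Sociable,-0.01,0.84,-0.13,-0.05
Affiliative/Companionable,-0.03,0.72,-0.16,-0.03
Solitary,0.32,-0.46,0.05,0.35
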