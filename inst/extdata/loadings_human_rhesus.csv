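item,Irritable,Exploratory,Apprehensive,Lazy
Irritable,0.92,-0.02,0.00,0.27
Aggressive,0.82,0.11,0.08,0.17
Excitable,0.81,0.20,-0.01,0.18
Feisty,0.80,0.24,0.05,0.17
Bullying,0.69,0.32,0.21,0.13
Reckless,0.65,0.26,0.25,0.25
Defiant,0.45,0.26,0.37,0.27
Unemotional,-0.68,0.13,-0.13,0.29
Understanding,-0.75,0.43,0.10,0.11
Tolerant,-0.82,0.19,0.16,0.25
Gentle,-0.83,-0.05,-0.01,0.27
Calm/Equable,-0.86,-0.02,0.07,0.29
Equable,-0.93,0.18,0.06,0.20
Curious/exploratory/inquisitive,-0.17,0.86,0.10,-0.09
Vigilant,0.05,0.84,-0.20,-0.01
Intelligent,-0.37,0.80,0.23,-0.05
Opportunistic,-0.04,0.80,0.17,0.03
Active/Energetic,0.12,0.76,0.18,-0.21
Impulsive,0.31,0.74,-0.10,-0.01
Eccentric,0.15,0.67,-0.21,0.19
Unpredictable,0.37,0.60,0.02,-0.04
Persistent,0.28,0.47,0.25,0.27
Confident,0.00,0.24,0.75,0.20
Strong,-0.05,-0.05,0.72,0.32
Bold,0.17,0.23,0.71,0.21
Effective,0.27,0.26,0.60,0.30
Direct/forceful/gets own way,0.37,0.32,0.51,0.28
Independent,-0.05,0.40,0.47,0.22
Insecure,0.14,-0.24,-0.61,0.19
Cautious,0.04,-0.01,-0.65,0.26
Timid,-0.12,-0.14,-0.69,0.38
Nervous/anxious/not calm,0.21,0.40,-0.73,0.07
Fearful,-0.01,0.05,-0.88,0.13
Apprehensive,0.08,0.15,-0.91,0.17
Lazy,-0.20,-0.48,-0.18,0.62
Slow,-0.30,-0.28,-0.20,0.61
Depressed,-0.17,-0.14,-0.41,0.43
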