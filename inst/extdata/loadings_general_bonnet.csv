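item,Confident,Active,Sociable,Equable
Irritable,0.41,0.00,-0.06,0.66
Bullying,0.81,-0.13,0.01,0.45
Excitable,-0.16,0.70,0.04,0.47
Jealous,0.66,-0.06,0.27,0.44
Stingy/greedy,0.58,-0.12,0.16,0.18
Feisty,0.64,0.19,-0.16,0.49
Unpredictable,0.21,0.45,-0.49,0.33
Aggressive,0.87,-0.13,-0.06,0.34
Persistent,0.77,0.23,0.02,0.12
Defiant,0.80,0.19,0.13,0.08
Impulsive,0.25,0.57,-0.31,0.40
Opportunistic,0.36,0.43,0.27,0.23
Apprehensive,-0.52,-0.23,-0.35,0.37
Nervous/anxious/not calm,-0.51,0.06,-0.22,0.62
Submissive/subordinate,-0.87,0.16,-0.15,0.10
Timid,-0.73,-0.23,-0.20,0.23
Cautious,-0.78,-0.38,0.04,0.12
Protective,0.77,-0.22,0.26,-0.09
Intelligent,0.59,-0.01,0.24,-0.31
Bold,0.74,0.42,-0.02,-0.11
Direct/forceful/gets own way,0.92,-0.10,0.07,-0.01
Confident,0.77,0.26,0.18,-0.21
Strong,0.87,-0.06,-0.44,-0.15
Effective,0.95,-0.10,0.03,0.03
Sociable,0.24,0.23,0.76,0.03
Affiliative/Companionable,0.19,0.20,0.80,0.03
Warm/affectionate,0.01,-0.10,0.81,-0.13
Nurturant,-0.09,-0.18,0.80,-0.10
Popular,0.58,0.14,0.50,-0.02
Manipulative,0.72,-0.10,0.16,0.23
Depressed,-0.20,-0.55,-0.52,0.01
Solitary,-0.15,-0.15,-0.81,-0.14
Lazy,-0.01,-0.78,-0.34,-0.08
Slow,0.06,-0.80,-0.30,-0.14
Curious/exploratory/inquisitive,0.18,0.87,-0.04,-0.16
Active/Energetic,0.00,0.85,0.15,0.06
Equable,0.20,-0.08,0.04,-0.81
Understanding,0.03,-0.24,0.59,-0.35
Calm/Equable,-0.02,-0.25,0.06,-0.68
Playful,-0.30,0.95,-0.12,-0.14
Gentle,-0.45,0.09,0.04,-0.65
Reckless,0.44,0.62,-0.34,0.19
Tense,-0.62,-0.26,-0.19,0.36
Unemotional,-0.10,-0.34,-0.47,-0.40
Eccentric,0.12,-0.06,-0.63,0.13
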