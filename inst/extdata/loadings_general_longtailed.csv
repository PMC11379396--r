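item,Confident,Sociable,Irritable/Equable,Active,Playful
Irritable,-0.04,0.03,0.95,-0.12,0.04
Bullying,0.36,0.05,0.66,0.10,0.24
Jealous,0.33,0.22,0.54,0.06,0.32
Stingy/greedy,0.58,-0.12,0.46,0.10,0.22
Feisty,0.12,0.03,0.84,0.09,0.08
Aggressive,0.40,0.10,0.70,0.07,0.23
Persistent,0.24,0.13,0.26,0.48,0.35
Defiant,0.14,0.15,0.37,0.38,0.21
Impulsive,-0.05,-0.06,0.43,0.55,0.13
Opportunistic,0.08,0.12,0.12,0.64,0.26
Fearful,-0.83,-0.12,0.08,-0.15,0.02
Apprehensive,-0.89,-0.05,0.04,-0.14,0.13
Nervous/anxious/not calm,-0.74,-0.05,0.31,0.05,0.10
Insecure,-0.75,0.44,0.21,-0.06,-0.04
Submissive/subordinate,-0.96,-0.06,-0.05,0.15,0.01
Timid,-0.83,-0.05,-0.01,-0.15,0.07
Cautious,-0.81,-0.02,0.00,-0.20,0.04
Protective,0.20,0.75,0.17,-0.04,0.20
Bold,0.82,0.03,0.11,0.06,0.18
Direct/forceful/gets own way,0.81,0.11,0.19,-0.02,0.21
Confident,0.90,0.06,-0.01,0.01,0.11
Strong,0.54,-0.04,0.14,0.10,0.46
Effective,0.78,0.18,0.12,0.08,0.16
Sociable,0.18,0.87,-0.03,0.08,-0.01
Affiliative/Companionable,0.20,0.82,-0.09,0.11,0.03
Warm/affectionate,0.02,0.91,-0.10,0.00,0.06
Nurturant,-0.18,0.91,-0.09,-0.03,0.11
Popular,0.46,0.67,-0.03,-0.04,0.11
Manipulative,0.11,0.31,0.31,0.25,0.34
Independent,0.31,-0.80,-0.15,0.00,0.41
Depressed,-0.62,-0.30,0.08,-0.32,0.30
Solitary,-0.43,-0.75,-0.04,-0.04,0.26
Lazy,-0.22,-0.10,0.01,-0.75,0.31
Slow,0.17,0.13,-0.09,-0.79,0.29
Curious/exploratory/inquisitive,0.08,0.05,-0.10,0.70,0.29
Active/Energetic,0.03,-0.09,-0.03,0.88,0.10
Tolerant,-0.10,0.59,-0.54,0.08,0.25
Equable,0.29,0.15,-0.76,-0.16,0.22
Understanding,0.13,0.23,-0.64,0.09,0.03
Calm/Equable,0.27,0.14,-0.80,-0.15,0.17
Playful,-0.15,0.24,-0.16,0.39,0.53
Gentle,-0.28,0.50,-0.57,-0.06,0.25
Reckless,-0.01,-0.02,0.25,0.54,0.21
Tense,-0.27,-0.13,0.40,-0.55,0.10
Unemotional,0.40,-0.10,-0.53,-0.26,0.26
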