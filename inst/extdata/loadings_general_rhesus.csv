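item,Irritable,Confident,Sociable,Active,Equable
Irritable,0.84,-0.01,-0.06,-0.02,-0.22
Bullying,0.79,-0.19,0.03,-0.06,-0.08
Excitable,0.77,0.08,0.04,-0.15,-0.09
Jealous,0.77,-0.13,0.18,0.00,-0.12
Stingy/greedy,0.75,-0.13,0.05,0.14,-0.11
Feisty,0.73,-0.06,0.11,-0.18,-0.15
Unpredictable,0.70,0.31,-0.19,-0.27,0.12
Aggressive,0.67,-0.30,-0.01,-0.05,-0.17
Persistent,0.64,-0.21,0.15,-0.02,0.04
Defiant,0.62,0.00,0.22,-0.17,0.01
Impulsive,0.54,0.18,-0.19,-0.47,0.27
Opportunistic,0.44,-0.13,0.19,-0.23,0.20
Fearful,0.03,0.91,-0.02,0.09,0.06
Apprehensive,0.08,0.91,0.11,0.10,0.02
Nervous/anxious/not calm,0.34,0.85,0.04,-0.06,0.02
Insecure,0.12,0.75,0.37,0.10,-0.12
Submissive/subordinate,-0.14,0.70,-0.22,0.11,0.27
Timid,-0.14,0.69,-0.03,0.26,0.17
Cautious,-0.13,0.68,-0.09,0.20,0.18
Protective,0.21,-0.53,0.38,0.15,0.24
Intelligent,0.09,-0.54,0.18,-0.25,0.43
Bold,0.54,-0.58,0.06,0.00,0.11
Direct/forceful/gets own way,0.48,-0.63,0.15,0.06,0.04
Confident,0.40,-0.66,0.13,-0.02,0.10
Strong,0.29,-0.68,-0.22,0.14,0.33
Effective,0.36,-0.72,0.19,0.13,0.03
Sociable,0.18,0.00,0.89,0.06,0.07
Affiliative/Companionable,0.14,0.10,0.88,0.09,0.15
Warm/affectionate,0.01,0.13,0.79,0.01,0.36
Nurturant,-0.08,0.07,0.71,0.03,0.35
Popular,0.11,-0.38,0.68,-0.08,0.11
Manipulative,0.48,-0.01,0.54,-0.05,-0.17
Independent,0.28,-0.43,-0.47,-0.05,0.39
Depressed,0.12,0.26,-0.56,0.49,0.24
Solitary,0.17,0.14,-0.72,0.13,0.45
Lazy,0.06,0.10,-0.04,0.90,0.11
Slow,-0.01,0.04,-0.04,0.86,0.16
Curious/exploratory/inquisitive,0.04,0.00,0.01,-0.63,0.50
Active/Energetic,0.25,-0.05,-0.18,-0.78,0.18
Tolerant,-0.30,0.10,0.30,0.11,0.65
Equable,-0.34,-0.08,0.13,0.22,0.65
Understanding,-0.19,-0.21,0.35,-0.03,0.65
Calm/Equable,-0.33,-0.09,0.13,0.35,0.61
Playful,-0.18,0.10,0.11,-0.42,0.58
Gentle,-0.41,0.12,0.32,0.15,0.57
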