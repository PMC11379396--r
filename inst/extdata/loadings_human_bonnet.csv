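item,Effective,Lazy/Exploratory,Apprehensive
Bullying,0.78,0.15,-0.04
Reckless,0.63,-0.36,0.28
Defiant,0.79,-0.20,0.01
Curious/exploratory/inquisitive,0.03,-0.87,-0.03
Opportunistic,0.28,-0.56,0.05
Active/Energetic,0.10,-0.87,0.08
Persistent,0.84,-0.10,0.11
Confident,0.49,-0.26,-0.37
Effective,0.95,0.06,0.06
Direct/forceful/gets own way,0.89,0.12,-0.09
Cautious,-0.52,0.34,0.27
Timid,-0.68,0.20,0.23
Nervous/anxious/not calm,0.00,-0.15,0.82
Apprehensive,-0.13,0.30,0.67
Lazy,0.04,0.89,0.04
Slow,0.11,0.88,-0.02
Depressed,-0.02,0.61,0.38
Submissive/subordinate,-0.70,-0.16,0.39
Tense,-0.31,0.22,0.55
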