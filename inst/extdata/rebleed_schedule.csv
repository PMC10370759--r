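# source: fixture
# synthetic annual re-bleed probabilities by year since presentation; constant tail
"year","prob"
1,0.35
2,0.1
3,0.05
4,0.04
5,0.03
6,0.03
7,0.03
8,0.03
9,0.03
10,0.03
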