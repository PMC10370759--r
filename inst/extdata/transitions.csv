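# source: fixture
# annual post-event transition rows equivalent to the default state-mortality rule
"from","to","prob"
"favorable","favorable",0.8933
"favorable","dead",0.1067
"unfavorable","unfavorable",0.2222
"unfavorable","dead",0.7778
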