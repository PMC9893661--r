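month,survival,p02_among_alive
12,0.83,0.44
24,0.74,0.46
36,0.66,0.48
48,0.58,0.5
60,0.5,0.52
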