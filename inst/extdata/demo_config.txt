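# demo pipeline configuration (synthetic community + proteome)
# score_max / margin are on the total-variation metric scale
score_max = 0.35
margin = 1.2
min_len = 1000
order = 3
identity = 0.95
top_fraction = 0.33
floor = auto
alpha = 0.05
fdr = 0.10
seed = 1
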