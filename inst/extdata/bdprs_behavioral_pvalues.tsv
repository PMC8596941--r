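outcome	p_uncorrected
rapm	0.388
tbit_total	1.000
digit_span	0.606
sa_total	0.010
sa_fluency	0.0002
sa_flexibility	0.050
sa_originality	0.171
sa_elaboration	0.058
word_color	1.000
color_word	0.132
reverse_stroop	0.126
stroop	0.206
bdi	0.280
poms_tmd	0.0002
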