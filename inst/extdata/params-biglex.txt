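excite_input_feature	0.25
excite_feature_phoneme	0.02
excite_phoneme_word	0.050000000000000003
feedback_word_phoneme	0.014999999999999999
inhibit_feature	0
inhibit_phoneme	0.040000000000000001
inhibit_word	0.025000000000000001
decay_feature	0.5
decay_phoneme	0.029999999999999999
decay_word	0.050000000000000003
rest_feature	-0.10000000000000001
rest_phoneme	-0.10000000000000001
rest_word	-0.10000000000000001
act_min	-0.29999999999999999
act_max	1
input_pattern_scale	4
n_slices	99
phoneme_spacing_slices	6
unit_copy_spacing	3
feature_spread_slices	11
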