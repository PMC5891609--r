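orthography	transcription
cat	k æ t
clue	k l u
dog	d o g
shoe	ʃ u
seed	s i d
lug	l ʌ g
bird	b ɜ r d
glass	g l æ s
strut	s t r ʌ t
ski	s k i
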