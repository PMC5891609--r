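phoneme	pow	voc	cns	voi	dif	acu	bur
p	0.2	0	1	0	0.8	0.2	1
b	0.3	0	1	1	0.8	0.2	0.8
t	0.2	0	1	0	0.9	0.9	1
d	0.3	0	1	1	0.9	0.9	0.8
k	0.2	0	1	0	0.2	0.35	1
g	0.3	0	1	1	0.2	0.35	0.8
s	0.4	0	0.8	0	0.9	0.95	0.3
S	0.4	0	0.8	0	0.6	0.7	0.3
r	0.7	0.6	0.5	1	0.4	0.5	0
l	0.7	0.6	0.5	1	0.55	0.65	0
a	1	1	0	1	0.1	0.3	0
i	1	1	0	1	1	0.95	0
u	1	1	0	1	0.7	0.05	0
^	0.9	1	0	1	0.4	0.4	0
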