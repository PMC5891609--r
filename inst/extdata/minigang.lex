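clue	k l u
clock	k l a k
clod	k l a d
clot	k l a t
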