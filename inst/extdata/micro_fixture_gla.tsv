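stimulus	lexicality	neighborhood	gla
care	word	high	0.65395388961823975
mint	word	low	0.37065180022562488
cade	nonword	high	0.50383413960195544
fost	nonword	low	0.00038001617690361963
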