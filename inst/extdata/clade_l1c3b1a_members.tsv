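id	origin
Toc293	Bolivia
Toc295	Bolivia
Toc304	Bolivia
Kenya1	Kenya
Zambia1	Zambia
Fang1	Fang
Pygmy1	Pygmy
Morocco1	Morocco
PuertoRico1	PuertoRico
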