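A	B	C	offset
6.51	-1.76	1.60	60
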