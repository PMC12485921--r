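protein	source	kind	start	end
AQP1	literature	TM	8	36
AQP1	literature	TM	49	66
AQP1	literature	TM	95	115
AQP1	literature	TM	137	155
AQP1	literature	TM	167	183
AQP1	literature	TM	208	228
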