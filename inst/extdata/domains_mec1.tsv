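name	start	end
kinase	1969	2368
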