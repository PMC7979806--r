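name	start	end
TRD3	2195	2475
kinase	2657	3056
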