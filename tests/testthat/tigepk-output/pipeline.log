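04:17:36 command=generate seed=1 tigepk=0.1.0 
04:17:36 stage generate 
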