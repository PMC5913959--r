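"artifact","path"
"dataset.csv","tigepk-output/dataset.csv"
"truth.yaml","tigepk-output/truth.yaml"
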