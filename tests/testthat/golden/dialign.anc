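1 2 1 1 2 20
1 2 4 4 1 10
1 3 1 2 2 20
2 3 1 2 2 20
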