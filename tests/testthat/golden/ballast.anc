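QUERY alpha
alpha beta 1 1 2 20
alpha beta 4 4 1 10
alpha gamma 1 2 2 20
beta gamma 1 2 2 20
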