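v0 v1 0.1
v0 v3 0.1
v2 v3 0.1
v1 v2 0.2
v1 v4 0.2
v2 v4 0.3
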