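raw_name,canonical_name
F2bis,F2
F4bis,F4
F5bis,F5
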