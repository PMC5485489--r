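# known drug targets (synthetic fixture)
T1
T2
T3
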