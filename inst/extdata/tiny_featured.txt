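# proteins with chemical-physical properties (synthetic fixture)
T1
T2
T3
P01
P02
P03
P04
P05
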