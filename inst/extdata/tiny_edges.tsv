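T1	T2
T1	T3
P01	T1
P02	T1
T2	T3
P01	T2
P02	T2
P01	T3
P02	T3
P01	P02
P03	P04
P03	P05
P03	P06
P03	P07
P04	P05
P04	P06
P04	P07
P05	P06
P05	P07
P06	P07
P01	P03
P07	P08
P08	P09
P09	P10
P10	P11
P10	P12
P11	P12
P12	P13
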