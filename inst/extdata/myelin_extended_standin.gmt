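MYELIN_EXTENDED	stand-in extended myelin-associated set: GO:0019911 members plus classic myelin genes	Mal	Mbp	Plp1	Tspan2	Mobp	Mog	Mag	Cnp	Cldn11	Sox10	Pllp	Ugt8
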