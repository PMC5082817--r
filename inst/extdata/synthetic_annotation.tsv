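level	category	signature_name
1	C01	SIG001
1	C02	SIG002
1	C03	SIG003
1	C04	SIG004
1	C01	SIG005
1	C02	SIG006
1	C03	SIG007
1	C04	SIG008
1	C01	SIG009
1	C02	SIG010
1	C03	SIG011
1	C04	SIG012
2	C01	SIG001
2	L2_C01	SIG002
2	L2_C01	SIG003
2	L2_C03	SIG004
2	C01	SIG005
2	L2_C08	SIG006
2	L2_C07	SIG007
2	L2_C02	SIG008
2	C01	SIG009
2	L2_C04	SIG010
2	L2_C01	SIG011
2	L2_C05	SIG012
3	C01	SIG001
3	L3_C04	SIG002
3	L3_C06	SIG003
3	L3_C03	SIG004
3	C01	SIG005
3	L3_C06	SIG006
3	L3_C01	SIG007
3	L3_C01	SIG008
3	C01	SIG009
3	L3_C05	SIG010
3	L3_C04	SIG011
3	L3_C04	SIG012
4	C01	SIG001
4	L4_C01	SIG002
4	L4_C02	SIG003
4	L4_C02	SIG004
4	C01	SIG005
4	L4_C01	SIG006
4	L4_C02	SIG007
4	L4_C02	SIG008
4	C01	SIG009
4	L4_C01	SIG010
4	L4_C02	SIG011
4	L4_C01	SIG012
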