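population	S_z	L_z	S_a	L_a	printed_fisher_p
A-Mar	33	3624	43	2956	0.048
C-It	29	3631	50	2957	0.0013
P-Spa	25	3631	34	2956	0.050
C-Hun	48	3641	57	2958	0.060
P-Nor	34	3641	43	2975	0.064
S-Bul	33	3626	49	2956	0.0072
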