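pop1	pop2	fst_z	fst_a	same_species
P-Spa	P-Nor	0.049	0.034	TRUE
P-Spa	C-Hun	0.692	0.420	FALSE
P-Nor	C-Hun	0.699	0.438	FALSE
P-Spa	C-It	0.703	0.484	FALSE
P-Nor	C-It	0.710	0.504	FALSE
C-Hun	C-It	0.016	0.020	TRUE
P-Spa	S-Bul	0.760	0.466	FALSE
P-Nor	S-Bul	0.763	0.498	FALSE
C-Hun	S-Bul	0.557	0.412	FALSE
C-It	S-Bul	0.578	0.441	FALSE
P-Spa	A-Mar	0.851	0.605	FALSE
P-Nor	A-Mar	0.853	0.629	FALSE
C-Hun	A-Mar	0.819	0.374	FALSE
C-It	A-Mar	0.827	0.382	FALSE
S-Bul	A-Mar	0.853	0.500	FALSE
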