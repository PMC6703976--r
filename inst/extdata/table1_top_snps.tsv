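snp_id	chromosome	position_bp	chisq	p_printed
AX-167952531	12	8184905	16.95	3.831E-5
AX-167543896	12	3268272	15.33	9.018E-5
AX-167539614	19	48026694	15.33	9.018E-5
AX-167921313	1	106754682	14.48	1.414E-4
AX-167811284	3	63770730	14.11	1.723E-4
AX-167798146	12	1936523	14.11	1.723E-4
AX-167837680	12	1939111	14.11	1.723E-4
AX-167809780	12	1950348	14.11	1.723E-4
AX-167698387	12	1956879	14.11	1.723E-4
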