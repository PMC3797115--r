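# apaswitch 0.1.0; stage=cooccur
mirna_a	mirna_b	n_rows_used	r_binary	p_binary	q_binary	r_weighted	p_weighted	q_weighted	computable
miR-a	miR-b	7	-0.353553390593274	0.436588061020382	0.436588061020382	-0.396329771192266	0.37874337101204	0.768975714422395	TRUE
miR-a	miR-c	6	NA	NA	NA	-0.147613967050826	0.780187294979178	0.780187294979178	FALSE
miR-b	miR-c	5	-0.612372435695795	0.272228401224416	0.436588061020382	-0.393139416420815	0.512650476281597	0.768975714422395	TRUE
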