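# apaswitch 0.1.0; stage=bootstrap, seed=7, kruskal_p=NA
mirna_id	true_r2	win_fraction	n_permutations	high_win
miR-a	0.661266732629088	0.8	200	FALSE
miR-b	0.533307796246299	0.635	200	FALSE
miR-c	0.999466598574477	0.94	200	FALSE
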