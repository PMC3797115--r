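# apaswitch 0.1.0; stage=scores
gene_id	mirna_id	score
G1	miR-b	0.3
G1	miR-c	0.3
G2	miR-b	1
G4	miR-a	-0.5
G4	miR-c	-0.5
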