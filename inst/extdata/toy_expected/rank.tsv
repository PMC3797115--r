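# apaswitch 0.1.0; stage=rank, enrichment_p=0.333333, n_negative=0, n_zero=0, n_positive=2
gene_id	rank	delta_len
G1	3	60
G2	4	200
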