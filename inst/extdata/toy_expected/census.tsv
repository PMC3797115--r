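# apaswitch 0.1.0; stage=census, n_genes_inspected=4
length_diff	n_genes
20	1
18	1
12	1
11	1
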