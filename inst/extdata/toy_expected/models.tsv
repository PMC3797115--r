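# apaswitch 0.1.0; stage=models
rank	predictors	bic	r_squared	n_genes
1	logfc_mrna+miR-c	-26.3388062704994	0.999466598574477	5
2	logfc_mrna+miR-a	5.92966358187403	0.661266732629088	5
3	logfc_mrna+miR-b	7.53194844191644	0.533307796246299	5
4	logfc_mrna	8.88092375768625	0.156674846661187	5
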