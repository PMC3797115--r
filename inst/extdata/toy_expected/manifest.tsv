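# apaswitch 0.1.0; day=3, cond_ct=CT, cond_in=IN, pseudocount=0.1, count_scale=1, search=exhaustive_within_significant, max_size=5, fdr=0.2, n_perm=200, win_threshold=0.95, seed=7, weight_condition=IN, min_rows=3, min_genes=3
file	md5
trend.tsv	540cd54bd33d684688bf318585c40007
scores.tsv	8cf36db72f0fc9c5b65d1ca85edfa7d4
census.tsv	c0b5d4ac0960ae9877a65f1fd990db3d
models.tsv	895d4ad23339732c3d783f621ec45f00
bootstrap.tsv	5f056c52a9cdd9a11f4987e8f8fd8809
cooccur.tsv	b86382370590cce58ff72f7a19890f0c
rank.tsv	41288acd8d57ab3c6939023a5c1cfb3d
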