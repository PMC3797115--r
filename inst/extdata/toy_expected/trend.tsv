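# apaswitch 0.1.0; stage=trend
gene_id	n_transcripts	delta_len	trend_r	cmh_stat	p_value	q_value	trend_class
G1	3	60	0.340502612303499	34.6666666666667	3.91274269719997e-09	7.82548539439993e-09	positive
G2	2	200	1	19	1.3071845366763e-05	1.7429127155684e-05	positive
G3	2	0	0	0	1	1	none
G4	2	-5.50000000000001	-0.489115988044522	35.6459330143546	2.36641407239874e-09	7.82548539439993e-09	negative
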