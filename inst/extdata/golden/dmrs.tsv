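# coordinates: 1-based inclusive
seq_id	start	end	context	dmc_count	level_a	level_b	meth_log2fc	direction	min_q
gene0002	301	600	CHH	12	0.0986301	0.332263	1.65568	hyper	1.28207e-37
gene0004	901	1250	CHH	10	0.397706	0.108108	-1.78742	hypo	2.17189e-31
gene0005	601	900	CHH	11	0.400783	0.0984043	-1.92196	hypo	3.41699e-50
gene0008	1001	1350	CHH	15	0.0837004	0.288299	1.67063	hyper	2.5113e-44
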