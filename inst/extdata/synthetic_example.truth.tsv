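gene_id	component	categories	n_codons
synthetic_example_g00001	large	RK	43
synthetic_example_g00002	large	F	31
synthetic_example_g00003	large	C	33
synthetic_example_g00004	small	NA	30
synthetic_example_g00005	large	I	42
synthetic_example_g00006	small	M	37
synthetic_example_g00007	large	NA	48
synthetic_example_g00008	large	C	34
synthetic_example_g00009	large	M	36
synthetic_example_g00010	large	E	41
synthetic_example_g00011	large	E	39
synthetic_example_g00012	large	NA	48
synthetic_example_g00013	large	T	60
synthetic_example_g00014	large	NA	40
synthetic_example_g00015	large	S	54
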