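synthetic_example_g00001	RK
synthetic_example_g00002	F
synthetic_example_g00003	C
synthetic_example_g00005	I
synthetic_example_g00006	M
synthetic_example_g00008	C
synthetic_example_g00009	M
synthetic_example_g00010	E
synthetic_example_g00011	E
synthetic_example_g00013	T
synthetic_example_g00015	S
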