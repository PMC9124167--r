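synthetic_example chromosome, complete genome - 1..50000
15 proteins
Location	Strand	Length	PID	Gene	Synonym	Code	COG	Product
1..129	+	42	1001	-	synthetic_example_g00001	-	COG0001RK	synthetic protein
180..272	+	30	1002	-	synthetic_example_g00002	-	COG0002F	synthetic protein
323..421	+	32	1003	-	synthetic_example_g00003	-	COG0003C	synthetic protein
472..561	+	29	1004	-	synthetic_example_g00004	-	-	synthetic protein
612..737	+	41	1005	-	synthetic_example_g00005	-	COG0005I	synthetic protein
788..898	+	36	1006	-	synthetic_example_g00006	-	COG0006M	synthetic protein
949..1092	+	47	1007	-	synthetic_example_g00007	-	-	synthetic protein
1143..1244	+	33	1008	-	synthetic_example_g00008	-	COG0008C	synthetic protein
1295..1402	+	35	1009	-	synthetic_example_g00009	-	COG0009M	synthetic protein
1453..1575	+	40	1010	-	synthetic_example_g00010	-	COG0010E	synthetic protein
1626..1742	+	38	1011	-	synthetic_example_g00011	-	COG0011E	synthetic protein
1793..1936	+	47	1012	-	synthetic_example_g00012	-	-	synthetic protein
1987..2166	+	59	1013	-	synthetic_example_g00013	-	COG0013T	synthetic protein
2217..2336	+	39	1014	-	synthetic_example_g00014	-	-	synthetic protein
2387..2548	+	53	1015	-	synthetic_example_g00015	-	COG0015S	synthetic protein
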