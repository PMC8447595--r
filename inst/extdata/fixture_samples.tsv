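sample_id	run_order	MS_batch	diet	replicate_group
s01	1	B1	A	NA
s02	2	B1	B	NA
s03	3	B1	A	R1
s04	4	B1	B	NA
s05	5	B1	A	R2
s06	6	B1	B	NA
s07	7	B2	A	NA
s08	8	B2	B	NA
s09	9	B2	A	R1
s10	10	B2	B	NA
s11	11	B2	A	R2
s12	12	B2	B	NA
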