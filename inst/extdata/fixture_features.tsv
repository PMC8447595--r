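feature_id	protein_id	is_spike_in
P1_a	P1	FALSE
P1_b	P1	FALSE
P2_a	P2	FALSE
P2_b	P2	FALSE
P3_a	P3	FALSE
P3_b	P3	FALSE
P4_a	P4	FALSE
P4_b	P4	FALSE
P5_a	P5	FALSE
P5_b	P5	FALSE
P6_a	P6	FALSE
P6_b	P6	FALSE
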