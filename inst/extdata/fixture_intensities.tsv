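feature_id	sample_id	intensity
P1_a	s01	20.6
P1_b	s01	19.9
P2_a	s01	19.2
P2_b	s01	18.4
P3_a	s01	22.5
P3_b	s01	22
P4_a	s01	19.6
P4_b	s01	18.9
P5_a	s01	21.4
P5_b	s01	21
P6_a	s01	20.9
P6_b	s01	20.5
P1_a	s02	21.3
P1_b	s02	20.9
P2_a	s02	18.1
P2_b	s02	17.5
P3_a	s02	23
P3_b	s02	22.4
P4_a	s02	19.3
P4_b	s02	19
P5_a	s02	21.3
P5_b	s02	20.9
P6_a	s02	20.8
P6_b	s02	20.5
P1_a	s03	20.3
P1_b	s03	19.8
P2_a	s03	18.8
P2_b	s03	18.1
P3_a	s03	22.3
P3_b	s03	21.9
P4_a	s03	19.2
P4_b	s03	18.8
P5_a	s03	21.3
P5_b	s03	20.8
P6_a	s03	20.8
P6_b	s03	20.4
P1_a	s04	21.2
P1_b	s04	20.7
P2_a	s04	17.6
P2_b	s04	17.3
P3_a	s04	22.5
P3_b	s04	22.2
P4_a	s04	19.2
P4_b	s04	18.6
P5_a	s04	21.2
P5_b	s04	20.6
P6_a	s04	20.5
P6_b	s04	20
P1_a	s05	20
P1_b	s05	19.5
P2_a	s05	18.5
P2_b	s05	18
P3_a	s05	22.2
P3_b	s05	21.4
P4_a	s05	19.1
P4_b	s05	18.6
P5_a	s05	21.1
P5_b	s05	20.5
P6_a	s05	20.5
P6_b	s05	20
P1_a	s06	20.9
P1_b	s06	20.1
P2_a	s06	17.5
P2_b	s06	17.1
P3_a	s06	22.5
P3_b	s06	22
P4_a	s06	18.9
P4_b	s06	18.5
P5_a	s06	21
P5_b	s06	20.3
P6_a	s06	20.4
P6_b	s06	20
P1_a	s07	21.7
P1_b	s07	20.6
P2_a	s07	18.5
P2_b	s07	18
P3_a	s07	22.9
P3_b	s07	22.3
P4_a	s07	20.6
P4_b	s07	20.1
P5_a	s07	20.7
P5_b	s07	19.9
P6_a	s07	21.1
P6_b	s07	20.6
P1_a	s08	22.4
P1_b	s08	21.8
P2_a	s08	17.7
P2_b	s08	16.9
P3_a	s08	23.3
P3_b	s08	22.8
P4_a	s08	20.5
P4_b	s08	19.9
P5_a	s08	20.9
P5_b	s08	20
P6_a	s08	20.9
P6_b	s08	20.5
P1_a	s09	21.5
P1_b	s09	20.6
P2_a	s09	18.4
P2_b	s09	17.6
P3_a	s09	22.8
P3_b	s09	22.2
P4_a	s09	20.7
P4_b	s09	19.9
P5_a	s09	20.5
P5_b	s09	19.8
P6_a	s09	20.9
P6_b	s09	20.4
P1_a	s10	22.1
P1_b	s10	21.2
P2_a	s10	17.2
P2_b	s10	16.7
P3_a	s10	23
P3_b	s10	22.5
P4_a	s10	20.3
P4_b	s10	19.7
P5_a	s10	20.4
P5_b	s10	20
P6_a	s10	20.8
P6_b	s10	20.1
P1_a	s11	21.1
P1_b	s11	20.3
P2_a	s11	18.1
P2_b	s11	17.3
P3_a	s11	22.1
P3_b	s11	21.7
P4_a	s11	20.2
P4_b	s11	19.4
P5_a	s11	20.3
P5_b	s11	19.5
P6_a	s11	20.8
P6_b	s11	20.1
P1_a	s12	22.1
P1_b	s12	21.3
P2_a	s12	16.9
P2_b	s12	16.6
P3_a	s12	22.8
P3_b	s12	22.2
P4_a	s12	20.1
P4_b	s12	19.3
P5_a	s12	20.2
P5_b	s12	19.5
P6_a	s12	20.6
P6_b	s12	20
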