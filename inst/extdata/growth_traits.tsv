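treatment	trait	mean	sd	letters
CW	plant_height_cm	11.60	0.32	a
CW	stem_diameter_mm	5.93	0.16	a
CW	leaf_area_cm2	82.23	1.94	b
CW	shoot_fresh_weight_g	14.99	0.61	b
CW	dry_weight_g	1.17	0.04	ab
CS	plant_height_cm	12.49	0.27	a
CS	stem_diameter_mm	6.31	0.19	a
CS	leaf_area_cm2	91.99	2.47	a
CS	shoot_fresh_weight_g	16.58	0.50	a
CS	dry_weight_g	1.30	0.05	a
HW	plant_height_cm	8.36	0.129	c
HW	stem_diameter_mm	5.41	0.10	b
HW	leaf_area_cm2	53.13	1.81	d
HW	shoot_fresh_weight_g	11.83	0.40	c
HW	dry_weight_g	0.95	0.04	c
HS	plant_height_cm	9.79	0.37	b
HS	stem_diameter_mm	5.87	0.13	a
HS	leaf_area_cm2	68.37	2.64	c
HS	shoot_fresh_weight_g	13.56	0.54	b
HS	dry_weight_g	1.08	0.06	bc
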