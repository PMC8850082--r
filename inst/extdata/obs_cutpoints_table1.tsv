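component	sex	t1	t2
fiber	male	12.56	19.70
fiber	female	10.10	16.31
carotene	male	98.83	306.25
carotene	female	98.08	383.50
riboflavin	male	1.79	2.69
riboflavin	female	1.34	2.02
niacin	male	20.65	29.75
niacin	female	14.52	21.86
vitamin_b6	male	1.59	2.40
vitamin_b6	female	1.13	1.77
folate	male	316.00	492.00
folate	female	251.00	388.96
vitamin_b12	male	3.36	6.20
vitamin_b12	female	2.22	4.22
vitamin_c	male	42.44	113.21
vitamin_c	female	38.01	98.49
vitamin_e	male	5.82	9.42
vitamin_e	female	4.53	7.52
calcium	male	646.00	1072.00
calcium	female	499.24	849.00
magnesium	male	257.00	361.28
magnesium	female	187.00	283.43
zinc	male	9.75	15.10
zinc	female	6.73	10.75
copper	male	1.12	1.57
copper	female	0.85	1.28
selenium	male	94.94	141.80
selenium	female	67.79	99.50
total_fat	male	69.83	107.43
total_fat	female	50.98	75.79
iron	male	12.88	19.17
iron	female	9.65	14.32
physical_activity	male	417.86	1135.71
physical_activity	female	270.00	845.71
bmi	male	25.54	29.17
bmi	female	23.74	28.64
cotinine	male	0.038	1.13
cotinine	female	0.035	0.172
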