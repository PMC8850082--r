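component	group	polarity	rule	units
fiber	dietary	antioxidant	sex_tertile	g/d
carotene	dietary	antioxidant	sex_tertile	RE/d
riboflavin	dietary	antioxidant	sex_tertile	mg/d
niacin	dietary	antioxidant	sex_tertile	mg/d
vitamin_b6	dietary	antioxidant	sex_tertile	mg/d
folate	dietary	antioxidant	sex_tertile	mcg/d
vitamin_b12	dietary	antioxidant	sex_tertile	mcg/d
vitamin_c	dietary	antioxidant	sex_tertile	mg/d
vitamin_e	dietary	antioxidant	sex_tertile	ATE mg/d
calcium	dietary	antioxidant	sex_tertile	mg/d
magnesium	dietary	antioxidant	sex_tertile	mg/d
zinc	dietary	antioxidant	sex_tertile	mg/d
copper	dietary	antioxidant	sex_tertile	mg/d
selenium	dietary	antioxidant	sex_tertile	mcg/d
total_fat	dietary	prooxidant	sex_tertile	g/d
iron	dietary	prooxidant	sex_tertile	mg/d
physical_activity	lifestyle	antioxidant	sex_tertile	MET-min/week
alcohol	lifestyle	prooxidant	fixed_alcohol	g/d
bmi	lifestyle	prooxidant	sex_tertile	kg/m^2
cotinine	lifestyle	prooxidant	sex_tertile	ng/mL
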