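fixture	class	sn1	sn2	sn3	abundance
fsolaris_pl	PC	16:0	16:1	NA	1.00
fsolaris_pl	PC	16:0	16:0	NA	0.80
fsolaris_pl	PC	14:0	16:0	NA	0.35
fsolaris_pl	PC	20:5	16:0	NA	0.90
fsolaris_pl	PC	20:5	16:1	NA	0.95
fsolaris_pl	PC	20:5	18:1	NA	0.60
fsolaris_pl	PC	20:5	18:2	NA	0.55
fsolaris_pl	PC	20:5	18:3	NA	0.50
fsolaris_pl	PC	20:5	18:4	NA	0.45
fsolaris_pl	PC	20:5	20:4	NA	0.40
fsolaris_pl	PC	20:5	20:5	NA	0.70
fsolaris_pl	PG	16:0	16:1	NA	0.60
fsolaris_pl	PG	16:1	16:1	NA	0.50
fsolaris_pl	PI	16:0	16:0	NA	0.40
fsolaris_gl	MGDG	14:0	16:1	NA	0.30
fsolaris_gl	MGDG	16:0	16:1	NA	0.90
fsolaris_gl	MGDG	16:1	16:1	NA	1.00
fsolaris_gl	MGDG	16:2	16:1	NA	0.70
fsolaris_gl	MGDG	16:3	16:1	NA	0.60
fsolaris_gl	MGDG	20:5	16:1	NA	0.80
fsolaris_gl	MGDG	20:5	16:2	NA	0.50
fsolaris_gl	MGDG	20:5	16:3	NA	0.45
fsolaris_gl	DGDG	16:0	16:0	NA	0.50
fsolaris_gl	DGDG	16:0	16:1	NA	0.80
fsolaris_gl	DGDG	16:1	16:1	NA	0.70
fsolaris_gl	DGDG	20:5	16:1	NA	0.60
fsolaris_gl	DGDG	20:5	16:2	NA	0.40
fsolaris_gl	SQDG	14:0	16:0	NA	0.40
fsolaris_gl	SQDG	16:0	16:0	NA	1.00
fsolaris_gl	SQDG	16:1	16:0	NA	0.70
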