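node_label	fossil	min_posteriori	max_posteriori	near_verdict	marshall_verdict	dornburg_verdict	evidence_assessment	min_priori	max_priori	attached	note
Testudines	Proterochersis robusta	210	NA	consistent	NA	omitted a priori	phyl. misplaced	155.6	251.4	TRUE	posteriori era lacks a root maximum; sampling runs attach 251.4
Pleurodira	Araripemys barretoi	110	134.4	consistent	NA	consistent	accurate minima	111	165.2	TRUE	NA
Pelomedusoides	Cearachelys placidoi	110	134.4	consistent	NA	consistent	accurate minima	92.8	149.5	TRUE	NA
Pelomedusidae	Pelusios rusingae	18	22.0	consistent	NA	inconsistent	inaccurately dated	5.3	149.5	TRUE	NA
Chelidae	Yaminuechelys gasparinii	71	86.7	inconsistent	NA	consistent	accurate minima	65.2	149.5	TRUE	NA
Chelodininae	Chelodina sp. and Elseya sp.	15	18.3	inconsistent	NA	inconsistent	accurate minima	11.6	149.5	TRUE	NA
Chelus_Phrynops	Chelus sp.	11.6	14.2	inconsistent	NA	inconsistent	accurate minima	13.4	149.5	TRUE	NA
Cryptodira	Sandownia harrisi	110	NA	consistent	NA	omitted a priori	phyl. misplaced	124	200.2	TRUE	NA
Trionychia	NA	NA	NA	NA	NA	NA	NA	124	177.6	TRUE	NA
Trionychidae	Aspideretes maortuensis	100	122.1	consistent	selected for calibration	consistent	phyl. untested	17.3	149.5	TRUE	NA
Durocryptodira	NA	NA	NA	NA	NA	NA	NA	88.6	149.5	TRUE	NA
Americhelydia	NA	NA	NA	NA	NA	NA	NA	70	149.5	TRUE	NA
Chelonioidea	Santanachelys gaffneyi	110	134.3	inconsistent	inconsistent	consistent/inconsistent	phyl. misplaced	48.4	149.5	TRUE	NA
Chelydroidea	NA	NA	NA	NA	NA	NA	NA	70	149.5	TRUE	NA
Kinosternoidea	Hoplochelys sp.	65	79.4	consistent	NA	consistent	accurate minima	70	149.5	TRUE	NA
Kinosternidae	Baltemys sp.	50	61.1	consistent	NA	consistent	accurate minima	52.8	149.5	TRUE	NA
Testudinoidea	NA	NA	NA	NA	NA	NA	NA	50.3	149.5	TRUE	NA
Emydidae_Platysternon	NA	NA	NA	NA	NA	NA	NA	32	100.5	TRUE	NA
Emydidae	Chrysemys antiqua	34	41.5	consistent	NA	consistent	accurate minima	32	100.5	TRUE	NA
Graptemys_Trachemys	Trachemys inflata	5	6.1	inconsistent	NA	inconsistent	phyl. untested	3	34	TRUE	NA
Testuguria	Hadrianus majusculus	52	63.5	consistent	NA	consistent	accurate minima	50.3	100.5	TRUE	NA
Heosemys_Mauremys	Ocadia crassa	50	61.1	inconsistent	NA	consistent	phyl. untested	5.3	65.8	TRUE	NA
Lindholmemydidae	NA	90	109.9	consistent	NA	consistent	phyl. untested	NA	NA	FALSE	no attachable node in the fixture topology
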