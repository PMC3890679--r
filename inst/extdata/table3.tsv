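query	vernacular	expected_species	family	status_iucn	percent_identity	status
q01	impepo	Helichrysum sp.	Asteraceae	-	100	match
q02	isihlalakahle	Harworthia limifolia	Asphodelaceae	Vulnerable (VU)	-	amplification_failed
q03	fembo	?	?	-	-	amplification_failed
q04	mkhanya kute	Vachellia xanthophloea	Fabaceae	Least Concern (LC)	98	match
q05	tindili	Entada rheedii	Fabaceae	Least Concern (LC)	99	match
q06	ubhonsi	Mappia racemosa	Icacinaceae	Vulnerable (VU)	89	mismatch
q07	ukhanyakute	Vachellia xanthophloea	Fabaceae	Least Concern (LC)	99	match
q08	umlilo	Stapelia gigantea	Apocynaceae	Least Concern (LC)	100	match
q09	malilisa	Holarrhena pubescens	Apocynaceae	Least Concern (LC)	100	mismatch
q10	umhlahlawehlathi	Cissus reniferus	Vitaceae	-	97	mismatch
q11	mphinde umshaye	Adenia gummifera	Passifloraceae	-	-	mismatch_unverifiable
q12	ube nam	Sarcostemma viminale	Asclepiadaceae	Least Concern (LC)	100	mismatch
q13	isikholokhota	Sanseviera hyacinthiodes	Asparagaceae	Least Concern (LC)	99	match
q14	mayime	Clivia miniata	Amaryllidaceae	Vulnerable (VU)	99	match
q15	umdletshane	Synadenium cupulare	Euphorbiaceae	Least Concern (LC)	100	match
q16	vuka	Myrothamnus flabellifolius	Myrothamnaceae	DDT	100	match
q17	umqotho	Boophane disticha	Amaryllidaceae	Declining	100	match
q18	imfingo	Stangeria eriopus	Stangeriaceae	Vulnerable (VU)	100	match
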