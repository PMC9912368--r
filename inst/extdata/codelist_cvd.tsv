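system	code	description	role
ICD10	I200	Unstable angina	DEFINING
ICD10	I21	Acute myocardial infarction	DEFINING
ICD10	I63	Cerebral infarction	DEFINING
OPCS4	K49	Transluminal balloon angioplasty of coronary artery	DEFINING
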