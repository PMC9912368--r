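system	code	description	role
ICD10	N00	Acute nephritic syndrome	EXCLUSION
ICD10	N18	Chronic kidney disease	DEFINING
READ_V2	K01..	Nephrotic syndrome	EXCLUSION
READ_V2	K05..	Chronic renal failure	DEFINING
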