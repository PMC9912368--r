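system	code	description	role
ICD10	H353	Degeneration of macula and posterior pole	EXCLUSION
ICD10	H360	Diabetic retinopathy	DEFINING
READ_V2	F420.	Diabetic retinopathy	DEFINING
READ_V2	F4200	Background diabetic retinopathy	DEFINING
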