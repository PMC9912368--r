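system	code	description	role
CTV3	X40J4	Type 2 diabetes mellitus	DEFINING
CTV3	X40J5	Type 1 diabetes mellitus	DEFINING
CTV3	X40JX	Maturity onset DM	DEFINING
CTV3	XE10E	Diabetes mellitus	DEFINING
READ_V2	66A..	Diabetic monitoring	DATE_ONLY
READ_V2	66A4.	Diabetic on insulin	DATE_ONLY
READ_V2	C10..	Diabetes mellitus	DEFINING
READ_V2	C100.	Diabetes mellitus with no mention of complication	DEFINING
READ_V2	C108.	Type 1 diabetes mellitus	DEFINING
READ_V2	C109.	Type 2 diabetes mellitus	DEFINING
READ_V2	C1090	Type 2 diabetes mellitus with renal complications	DEFINING
TPP_LOCAL	Y1234	Diabetes annual review	DATE_ONLY
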