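system	code	biomarker
READ_V2	44g1.	GLUCOSE
READ_V2	42W5.	HBA1C
READ_V2	46N4.	URINE_ALBUMIN
READ_V2	46M7.	URINE_CREATININE
READ_V2	44J3.	SERUM_CREATININE
READ_V2	2469.	SBP
READ_V2	246A.	DBP
READ_V2	44P..	TOTAL_CHOL
READ_V2	44P5.	HDL
READ_V2	44P6.	LDL
READ_V2	44Q..	TRIG
READ_V2	46TC.	UACR
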